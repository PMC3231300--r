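#!/usr/bin/env Rscript
# Ask whether the first principal component of the simulated profile matrix
# is the hedonic dimension: normalize, autoscale, PCA, cross-validated Q2,
# loading-tone correlation, and the combined verdict - then repeat with
# shuffled tones as a negative control.

suppressMessages(library(odorhedonics))
seed <- 20260103

profile <- read_profile_matrix("results/synthetic/general/profile.csv")
vocab <- read_vocabulary("results/synthetic/general/vocabulary.csv")

res <- run_hedonic_dimension(profile, vocab, seed = seed)
print(res$decision)

loadings <- data.frame(descriptor = rownames(res$pca$loadings),
                       res$pca$loadings, check.names = FALSE)
write.csv(loadings, "results/synthetic/general/pc_loadings.csv",
          row.names = FALSE)
write.csv(data.frame(component = paste0("PC", seq_along(res$q2)),
                     eigenvalue = res$pca$eigenvalues,
                     explained_variance = res$pca$explained_variance,
                     q2 = res$q2),
          "results/synthetic/general/pca_summary.csv", row.names = FALSE)

# quadratic loading-tone relation through the origin
tones <- unname(vocab[rownames(res$pca$loadings)])
lt <- fit_loading_tone_quadratic(res$pca$loadings[, 1], tones)
message(sprintf(
  "Loading-tone parabola through the origin: p1 = %.4f HT %+.4f HT^2 (R2 = %.2f)",
  lt$coefficients["linear"], lt$coefficients["quadratic"], lt$r_squared))
if (length(lt$outliers) > 0)
  message("Loading-tone outliers: ", paste(lt$outliers, collapse = ", "))

# negative control: shuffling tones must destroy the association
set.seed(seed)
v_shuf <- hedonic_vocabulary(names(vocab), sample(unname(vocab)))
res_shuf <- run_hedonic_dimension(profile, v_shuf, seed = seed)
message(sprintf(
  "Shuffled-tone control: loading-tone r = %.3f, verdict %s (planted: r = %.3f, verdict %s)",
  res_shuf$decision$loading_tone_r, res_shuf$decision$is_pc1_hedonic,
  res$decision$loading_tone_r, res$decision$is_pc1_hedonic))

write.csv(data.frame(
  run = c("planted", "shuffled"),
  loading_tone_r = c(res$decision$loading_tone_r,
                     res_shuf$decision$loading_tone_r),
  loading_tone_p = c(res$decision$loading_tone_p,
                     res_shuf$decision$loading_tone_p),
  verdict = c(res$decision$is_pc1_hedonic, res_shuf$decision$is_pc1_hedonic)),
  "results/synthetic/general/hedonic_dimension_verdict.csv",
  row.names = FALSE)
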