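#!/usr/bin/env Rscript
# Score the simulated profile matrix with the tone-weighted-average
# estimator, compare the estimates against the planted truth, and fit the
# affine calibration between the two score routes.

suppressMessages(library(odorhedonics))

profile <- read_profile_matrix("results/synthetic/general/profile.csv")
vocab <- read_vocabulary("results/synthetic/general/vocabulary.csv")
truth <- read.csv("results/synthetic/general/truth.csv")

run <- run_profile_to_hedonics(profile, vocab)
write_score_table(run$scores, "results/synthetic/general/eq1_scores.csv")

merged <- merge(run$scores, truth, by = "id", suffixes = c("_eq1", "_truth"))
ok <- is.finite(merged$hedonic_score_eq1)
cmp <- compare_scores(merged$hedonic_score_truth[ok],
                      merged$hedonic_score_eq1[ok])
message(sprintf(
  "Weighted-average estimates track the planted truth: r = %.3f (n = %d, p = %.2g)",
  cmp$r, cmp$n, cmp$p_value))
message(sprintf("Calibration line: estimate = %.3f + %.3f * truth",
                cmp$intercept, cmp$slope))

cal <- fit_score_calibration(merged$hedonic_score_eq1[ok],
                             merged$hedonic_score_truth[ok])
message(sprintf(
  "Inverse calibration (truth on estimate): intercept %.3f, slope %.3f, R2 = %.3f",
  cal$coefficients[1], cal$coefficients[2], cal$r_squared))

write.csv(data.frame(
  quantity = c("r", "slope", "intercept", "n_scored", "n_odorless"),
  value = c(cmp$r, cmp$slope, cmp$intercept, sum(ok), run$n_odorless)),
  "results/synthetic/general/score_vs_truth.csv", row.names = FALSE)
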