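test_that("autoscaling centers and scales with the n-1 divisor", {
  m <- matrix(c(0, 10, 2, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  s <- autoscale(m)
  expect_equal(unname(s[, "a"]), c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_equal(colMeans(s), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(s, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # idempotent on already-autoscaled data
  expect_equal(unname(autoscale(s)), unname(s), tolerance = 1e-12,
               ignore_attr = TRUE)
  mm <- cbind(m, const = c(3, 3))
  expect_error(autoscale(mm), "const")
})

test_that("normality transforms honour overrides and the skewness rule", {
  set.seed(5)
  skewed <- rexp(200)^2              # heavy right skew -> log
  mild <- runif(200)^1.2             # mild positive skew -> sqrt
  m <- cbind(musky = skewed, fruity = mild)
  out <- transform_for_normality(m)
  log_tab <- attr(out, "transform_log")
  expect_identical(log_tab$transform[log_tab$column == "musky"], "log")
  expect_equal(unname(out[, "musky"]), log(skewed + 1))
  # explicit override wins over the automatic rule
  out2 <- transform_for_normality(m, overrides = c(musky = "sqrt"))
  expect_equal(unname(out2[, "musky"]), sqrt(skewed))
  # all-zero column: sqrt leaves it unchanged, log maps to log(1) = 0
  z <- cbind(zero = rep(0, 5), x = c(1, 2, 3, 4, 50))
  expect_equal(unname(transform_for_normality(
    z, overrides = c(zero = "sqrt"))[, "zero"]), rep(0, 5))
  expect_equal(unname(transform_for_normality(
    z, overrides = c(zero = "log"))[, "zero"]), rep(log(1), 5))
  expect_error(transform_for_normality(cbind(a = c(-1, 2))), "negative")
  expect_error(transform_for_normality(m, overrides = c(nosuch = "log")),
               "unknown column")
})

test_that("PCA matches an independent eigendecomposition on a small case", {
  m <- matrix(c(2.1, 0.5, 1.0,
                0.3, 2.9, 0.4,
                1.5, 1.1, 2.2,
                0.2, 0.7, 0.9,
                2.8, 1.9, 0.1), 5, 3, byrow = TRUE,
              dimnames = list(paste0("o", 1:5), c("a", "b", "c")))
  pca <- run_pca(m, n_components = 3)
  eg <- eigen(cov(m))  # oracle: eigendecomposition of the covariance
  expect_equal(pca$eigenvalues, eg$values, tolerance = 1e-8)
  for (k in 1:3) {
    expect_equal(abs(as.numeric(pca$loadings[, k])), abs(eg$vectors[, k]),
                 tolerance = 1e-8, info = paste("component", k))
  }
  # loadings orthonormal; score variances equal eigenvalues
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(apply(pca$scores, 2, var)), pca$eigenvalues,
               tolerance = 1e-10)
})

test_that("PCA reconstruction, rank-1 variance and duplication invariances hold", {
  set.seed(17)
  base <- matrix(rnorm(60), 10, 6,
                 dimnames = list(paste0("o", 1:10), paste0("d", 1:6)))
  s <- autoscale(base)
  pca <- run_pca(s, n_components = 6)
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(unname(recon), unname(s), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalue sum equals the number of variables on autoscaled data
  expect_equal(sum(pca$eigenvalues), 6, tolerance = 1e-8)
  # rank-1 matrix: PC1 explains all variance (no autoscaling)
  r1 <- outer(1:8, c(1, 2, 3)) + 0
  dimnames(r1) <- list(paste0("o", 1:8), paste0("d", 1:3))
  p1 <- run_pca(r1, n_components = 2)
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-10)
  # duplicated rows leave loadings unchanged (up to sign convention)
  dup <- rbind(base, base)
  rownames(dup) <- paste0("o", 1:20)
  pd <- run_pca(dup, n_components = 3)
  pb <- run_pca(base, n_components = 3)
  for (k in 1:3) {
    expect_equal(abs(as.numeric(pd$loadings[, k])),
                 abs(as.numeric(pb$loadings[, k])), tolerance = 1e-8)
  }
  expect_error(run_pca(s, n_components = 11), "exceeds")
})

test_that("PC1 orientation makes the loading-tone correlation non-negative", {
  set.seed(23)
  cfg <- generator_config(n_molecules = 80, seed = 301)
  st <- simulate_study(cfg)
  cleaned <- clean_profile(st$profile)
  s <- autoscale(unclass(cleaned))
  tones <- st$vocabulary[colnames(cleaned)]
  p <- run_pca(s, 2, tones = tones)
  expect_gte(cor(p$loadings[, 1], unname(tones)), 0)
  # flipping the input sign of the data leaves the oriented PC1 output stable
  p_flip <- run_pca(-s, 2, tones = tones)
  expect_gte(cor(p_flip$loadings[, 1], unname(tones)), 0)
})

test_that("Q2 is high for planted structure, low for pure noise, never above 1", {
  set.seed(41)
  # noiseless rank-1 data
  r1 <- outer(rnorm(30), rnorm(7))
  q_r1 <- q2_cross_validation(r1, n_components = 1, folds = 5, seed = 9)
  expect_gt(q_r1[1], 0.9)
  expect_lte(q_r1[1], 1)
  # pure standard-normal noise: nothing to predict
  noise <- matrix(rnorm(700), 100, 7)
  q_noise <- q2_cross_validation(noise, n_components = 2, folds = 5, seed = 9)
  expect_lte(q_noise[1], 0.05)
  # monotone degradation: adding noise to low-rank data cannot help
  noisy <- r1 + matrix(rnorm(210, 0, 0.8), 30, 7)
  q_noisy <- q2_cross_validation(noisy, n_components = 1, folds = 5, seed = 9)
  expect_gte(q_r1[1], q_noisy[1])
  expect_error(q2_cross_validation(r1, folds = 1, seed = 1), "2 folds")
  expect_error(q2_cross_validation(r1, folds = 31, seed = 1), "more folds")
})

test_that("no-intercept quadratic loading-tone fit matches the normal equations", {
  # exact recovery of a planted parabola through the origin
  ht <- c(-3.2, -1.5, 0.4, 1.8, 3.1)
  p_exact <- 0.0309 * ht - 0.0046 * ht^2
  fit <- fit_loading_tone_quadratic(p_exact, ht)
  expect_equal(unname(fit$coefficients), c(0.0309, -0.0046), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # 5-point noisy instances agree with an independent normal-equations solve
  set.seed(53)
  for (rep in 1:10) {
    htr <- runif(5, -4, 4)
    pr <- 0.0309 * htr - 0.0046 * htr^2 + rnorm(5, 0, 0.01)
    got <- fit_loading_tone_quadratic(pr, htr)
    expect_equal(unname(got$coefficients), oracle_quadratic_origin(pr, htr),
                 tolerance = 1e-10)
  }
  expect_error(fit_loading_tone_quadratic(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_loading_tone_quadratic(c(1, 2, 3), rep(0, 3)), "singular")
})

test_that("hedonic decision is positive for planted structure, negative after shuffling", {
  cfg <- generator_config(n_molecules = 150, seed = 77)
  st <- simulate_study(cfg)
  res <- run_hedonic_dimension(st$profile, st$vocabulary, seed = 13)
  expect_true(res$decision$is_pc1_hedonic)
  expect_gt(res$decision$loading_tone_r, 0.8)
  # shuffled tones destroy the association
  set.seed(101)
  v_shuf <- hedonic_vocabulary(names(st$vocabulary),
                               sample(unname(st$vocabulary)))
  res_shuf <- run_hedonic_dimension(st$profile, v_shuf, seed = 13)
  expect_false(res_shuf$decision$is_pc1_hedonic)
  expect_lt(abs(res_shuf$decision$loading_tone_r),
            res$decision$loading_tone_r)
  # perfect monotone case: loadings proportional to tones -> r = 1
  pca_stub <- structure(list(
    loadings = matrix(c(-2, -1, 0.5, 1.5, 3) * 0.1, ncol = 1,
                      dimnames = list(paste0("d", 1:5), "PC1")),
    scores = matrix(0, 2, 1), eigenvalues = 2, explained_variance = 1,
    n = 2), class = "pca_result")
  dec <- hedonic_decision(pca_stub, c(-2, -1, 0.5, 1.5, 3))
  expect_equal(dec$loading_tone_r, 1, tolerance = 1e-12)
})
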