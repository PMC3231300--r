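test_that("preset registry carries the published coefficients verbatim", {
  reg <- preset_equations()
  expect_identical(sort(names(reg)), sort(c("eq7", "eq8", "eq9", "eq10",
                                            "eq11", "eq12")))
  expect_identical(reg$eq7$coefficients,
                   c("(Intercept)" = -2.56, n_at = 0.23, i_ox = 1.26,
                     i_sul = -1.54))
  expect_identical(reg$eq11$coefficients,
                   c("(Intercept)" = -2.33, n_at = 0.33, n_at_sq = -0.0104,
                     i_ox_nat = 0.057, i_sul = -0.83, i_acid = -1.62))
  expect_identical(reg$eq12$coefficients,
                   c("(Intercept)" = -1.85, n_at = 0.35, n_at_sq = -0.014,
                     i_ox_nat = 0.041))
  expect_match(reg$eq10$advisory, "not recommended")
  expect_identical(reg$eq8$scale, "PR")
  # registry is rebuilt per call: mutating a copy cannot corrupt it
  reg$eq7$coefficients["n_at"] <- 99
  expect_equal(preset_equations()$eq7$coefficients[["n_at"]], 0.23)
})

test_that("preset predictions are exact linear combinations", {
  expect_equal(predict_hedonic("eq7", feature_row(10, i_ox = 1))$hedonic_score,
               1.00, tolerance = 1e-12)
  expect_equal(predict_hedonic("eq9", feature_row(4, i_ox = 1,
                                                  i_acid = 1))$hedonic_score,
               -2.62 + 0.92 + 1.58 - 2.58, tolerance = 1e-12)
  expect_equal(predict_hedonic("eq12", feature_row(0))$hedonic_score, -1.85,
               tolerance = 1e-12)
  expect_error(predict_hedonic("eq99", feature_row(5)), "unknown preset")
})

test_that("eq8 round-trips to eq9 through the ranking calibration", {
  # eq9 was derived by pushing eq8 (ranking scale) through H = 7.11 - 0.091 PR
  set.seed(61)
  for (rep in 1:20) {
    f <- feature_row(sample(2:20, 1), i_ox = rbinom(1, 1, 0.7),
                     i_sul = rbinom(1, 1, 0.2), i_acid = 0,
                     i_amine = rbinom(1, 1, 0.2))
    if (f$i_acid == 1) f$i_ox <- 1
    pr <- predict_hedonic("eq8", f)$hedonic_score
    h_via_cal <- 7.11 - 0.091 * pr
    h_direct <- predict_hedonic("eq9", f)$hedonic_score
    # coefficients were rounded when printed; agreement is to ~2 decimals
    expect_lt(abs(h_via_cal - h_direct), 0.06)
  }
})

test_that("model fitting recovers preset coefficients exactly on noiseless data", {
  set.seed(71)
  n <- 60
  f <- data.frame(id = sprintf("m%02d", 1:n),
                  n_at = sample(1:21, n, replace = TRUE),
                  i_ox = rbinom(n, 1, 0.7), i_sul = rbinom(n, 1, 0.2),
                  i_acid = 0, i_amine = 0)
  y <- predict_hedonic("eq7", f)$hedonic_score
  fit <- fit_hedonic_model(f, y, terms = c("(Intercept)", "n_at", "i_ox",
                                           "i_sul"))
  expect_equal(fit$coefficients,
               c("(Intercept)" = -2.56, n_at = 0.23, i_ox = 1.26,
                 i_sul = -1.54), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("parameter recovery within 3 SE on noisy simulated data", {
  set.seed(73)
  n <- 200
  f <- data.frame(id = sprintf("m%03d", 1:n),
                  n_at = sample(1:21, n, replace = TRUE),
                  i_ox = rbinom(n, 1, 0.7), i_sul = rbinom(n, 1, 0.15),
                  i_acid = 0, i_amine = 0)
  truth <- preset_equations()$eq7$coefficients
  y <- predict_hedonic("eq7", f)$hedonic_score + rnorm(n, 0, 0.8)
  fit <- fit_hedonic_model(f, y, terms = names(truth))
  z <- abs(fit$coefficients - truth) / fit$se
  expect_true(all(z < 3), info = paste(round(z, 2), collapse = " "))
})

test_that("degenerate designs and undetermined indicators are rejected", {
  f <- data.frame(id = c("a", "b", "c", "d", "e"), n_at = c(2, 5, 9, 12, 20),
                  i_ox = 1, i_sul = 0, i_acid = NA, i_amine = 0)
  y <- c(-1, 0, 1, 1.5, 2)
  # i_ox constant and intercept present -> collinear
  expect_error(fit_hedonic_model(f, y, terms = c("(Intercept)", "i_ox")),
               "collinear")
  expect_error(fit_hedonic_model(f, y, terms = c("(Intercept)", "n_at",
                                                 "i_acid")),
               "undetermined")
  expect_error(predict_hedonic("eq9", f), "undetermined")
})

test_that("influential points are reported and only excluded on opt-in", {
  set.seed(79)
  n <- 40
  f <- data.frame(id = sprintf("m%02d", 1:n),
                  n_at = c(sample(2:12, n - 1, replace = TRUE), 29),
                  i_ox = 1, i_sul = 0, i_acid = 0, i_amine = 0)
  y <- -2 + 0.3 * f$n_at + rnorm(n, 0, 0.3)
  y[n] <- y[n] - 6  # the largest molecule misbehaves
  fit <- fit_hedonic_model(f, y, terms = c("(Intercept)", "n_at"))
  expect_true(sprintf("m%02d", n) %in% fit$diagnostics$influential$id)
  refit <- fit_hedonic_model(f, y, terms = c("(Intercept)", "n_at"),
                             exclude = "influential")
  expect_equal(refit$n, n - nrow(fit$diagnostics$influential))
  # with no influential points, opt-in refit changes nothing
  clean_y <- -2 + 0.3 * f$n_at[1:(n - 1)] + rnorm(n - 1, 0, 0.2)
  fit_a <- fit_hedonic_model(f[1:(n - 1), ], clean_y,
                             terms = c("(Intercept)", "n_at"))
  fit_b <- fit_hedonic_model(f[1:(n - 1), ], clean_y,
                             terms = c("(Intercept)", "n_at"),
                             exclude = "influential")
  expect_equal(fit_a$coefficients, fit_b$coefficients, tolerance = 1e-12)
  expect_false(is.null(fit_a$diagnostics$residual_normality))
})

test_that("null crossings match the closed forms and the numeric scan oracle", {
  expect_equal(null_crossing("eq7")$threshold, (2.56 - 1.26) / 0.23,
               tolerance = 1e-12)
  expect_equal(null_crossing("eq9")$threshold, (2.62 - 1.58) / 0.23,
               tolerance = 1e-12)
  for (id in c("eq7", "eq9", "eq10", "eq11", "eq12")) {
    closed <- null_crossing(id)
    scanned <- oracle_root_scan(id)
    expect_equal(closed$roots, scanned, tolerance = 1e-6, info = id)
  }
  # quadratics: the larger root is flagged as extrapolation
  cr11 <- null_crossing("eq11")
  expect_false(is.null(cr11$extrapolation_flag))
  expect_gt(cr11$extrapolation_flag, 29)
  # a flat model has no crossing (result, not an error)
  flat <- odorhedonics:::.new_model(c("(Intercept)" = 1, n_at = 0),
                                    provenance = "fitted")
  expect_false(null_crossing(flat)$crossing)
})

test_that("size optima match the vertex formula; linear models are monotone", {
  expect_equal(optimum_nat("eq12")$nat_opt, (0.35 + 0.041) / (2 * 0.014),
               tolerance = 1e-12)
  expect_equal(optimum_nat("eq11")$nat_opt, (0.33 + 0.057) / (2 * 0.0104),
               tolerance = 1e-12)
  expect_identical(optimum_nat("eq7")$kind, "monotone")
  up <- odorhedonics:::.new_model(c("(Intercept)" = 0, n_at = 0.1,
                                    n_at_sq = 0.01), provenance = "fitted")
  expect_identical(optimum_nat(up)$kind, "unbounded")
  # the optimum is a genuine maximum of the prediction on a grid
  o12 <- optimum_nat("eq12")
  grid_scores <- predict_hedonic("eq12", feature_row(1:40, i_ox = 1,
    id = paste0("g", 1:40)))$hedonic_score
  expect_lte(max(grid_scores), o12$max_score + 1e-12)
})

test_that("preset predictions respect the monotone functional-group effects", {
  grid <- 1:40
  for (id in c("eq7", "eq9", "eq10")) {
    sc <- predict_hedonic(id, feature_row(grid, i_ox = 1,
      id = paste0("g", grid)))$hedonic_score
    expect_true(all(diff(sc) > 0), info = paste(id, "increasing in size"))
  }
  for (id in c("eq11", "eq12")) {
    sc <- predict_hedonic(id, feature_row(grid, i_ox = 1,
      id = paste0("g", grid)))$hedonic_score
    v <- optimum_nat(id)$nat_opt
    expect_true(all(diff(sc[grid <= floor(v)]) > 0), info = id)
    expect_true(all(diff(sc[grid >= ceiling(v)]) < 0), info = id)
  }
  # sulfur or an acid group never raises a prediction; oxygen never lowers it
  set.seed(83)
  for (id in c("eq7", "eq9", "eq10", "eq11", "eq12")) {
    nat <- sample(2:25, 10, replace = TRUE)
    base <- predict_hedonic(id, feature_row(nat, i_ox = 1,
      id = paste0("b", 1:10)))$hedonic_score
    plus_s <- predict_hedonic(id, feature_row(nat, i_ox = 1, i_sul = 1,
      id = paste0("s", 1:10)))$hedonic_score
    expect_true(all(plus_s <= base + 1e-12), info = paste(id, "sulfur"))
    no_ox <- predict_hedonic(id, feature_row(nat,
      id = paste0("n", 1:10)))$hedonic_score
    expect_true(all(no_ox <= base + 1e-12), info = paste(id, "oxygen"))
    if ("i_acid" %in% names(preset_equations()[[id]]$coefficients)) {
      plus_a <- predict_hedonic(id, feature_row(nat, i_ox = 1, i_acid = 1,
        id = paste0("a", 1:10)))$hedonic_score
      expect_true(all(plus_a <= base + 1e-12), info = paste(id, "acid"))
    }
  }
})

test_that("pleasant classification uses a strict zero threshold", {
  cls <- classify_pleasant(c(1.0, -0.5, 0.2))
  expect_equal(cls$fraction_pleasant, 2 / 3)
  expect_equal(cls$n, 3)
  expect_false(classify_pleasant(0)$classes[1])
  expect_error(classify_pleasant(NA_real_), "no finite")
})

test_that("score comparison reports r, p and a slope CI that covers truth", {
  x <- seq(-2, 2, length.out = 20)
  same <- compare_scores(x, x)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_equal(same$slope, 1, tolerance = 1e-10)
  expect_equal(same$intercept, 0, tolerance = 1e-10)
  anti <- compare_scores(x, -x)
  expect_equal(anti$r, -1, tolerance = 1e-12)
  set.seed(89)
  a <- runif(150, -3, 3)
  b <- 0.26 + 1.03 * a + rnorm(150, 0, 0.5)
  cmp <- compare_scores(a, b)
  expect_gt(cmp$r, 0.9)
  expect_lt(cmp$conf_int["a", 1], 1.03)
  expect_gt(cmp$conf_int["a", 2], 1.03)
  expect_error(compare_scores(rep(1, 5), 1:5), "zero variance")
})
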