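# Shared fixtures and independent oracles, all built in code.

# Two-descriptor worked example: 36% fruity, 8% sweet.
fixture_benzyl_acetate <- function() {
  m <- odor_profile_matrix(matrix(c(36, 8), 1, 2,
    dimnames = list("benzyl acetate", c("fruity", "sweet"))))
  v <- hedonic_vocabulary(c("fruity", "sweet"), c(2.23, 2.03))
  list(profile = m, vocabulary = v)
}

# Small profile matrix with mixed-tone descriptors for clean-up tests.
fixture_small_profile <- function() {
  m <- matrix(c(
    40, 3, 10, 0,
    5, 60, 0, 2,
    12, 8, 30, 3.9
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("o1", "o2", "o3"), c("fruity", "sulfidic", "sweet", "fishy")))
  odor_profile_matrix(m)
}

# Independent normal-equations solver for the no-intercept quadratic fit.
oracle_quadratic_origin <- function(p, ht) {
  X <- cbind(ht, ht^2)
  as.numeric(solve(t(X) %*% X, t(X) %*% p))
}

# Independent dense root scan for prediction polynomials in n_at: sign
# changes on a fine grid refined by bisection.
oracle_root_scan <- function(model, i_ox = 1, i_sul = 0, i_acid = 0,
                             i_amine = 0, lower = 1e-9, upper = 100) {
  pred <- function(x) {
    f <- data.frame(id = paste0("g", seq_along(x)), n_at = x, i_ox = i_ox,
                    i_sul = i_sul, i_acid = i_acid, i_amine = i_amine)
    predict_hedonic(model, f)$hedonic_score
  }
  grid <- seq(lower, upper, length.out = 20001)
  y <- pred(grid)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (y[i] == 0) roots <- c(roots, grid[i])
    if (y[i] * y[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(pred, c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  sort(unique(roots))
}

# Feature row helper for prediction tests.
feature_row <- function(n_at, i_ox = 0, i_sul = 0, i_acid = 0, i_amine = 0,
                        id = "x") {
  data.frame(id = id, n_at = n_at, i_ox = i_ox, i_sul = i_sul,
             i_acid = i_acid, i_amine = i_amine, stringsAsFactors = FALSE)
}
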