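# PCA-based extraction of a candidate hedonic dimension from odor-profile
# matrices: normalizing transforms, autoscaling, component retention by
# eigenvalue and cross-validated Q2, and the loading-tone decision rule.

#' Autoscale a profile matrix
#'
#' Mean-centers each column and scales it to unit variance (divisor n - 1),
#' the standard pretreatment before PCA of profile data.
#'
#' @param m Numeric matrix.
#' @return Scaled matrix with attributes `centers` and `scales`.
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  s <- apply(m, 2, stats::sd)
  if (any(s == 0)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(m)[s == 0], collapse = ", ")), call. = FALSE)
  }
  out <- scale(m, center = TRUE, scale = TRUE)
  structure(out[, , drop = FALSE],
            centers = attr(out, "scaled:center"),
            scales = attr(out, "scaled:scale"),
            dimnames = dimnames(m))
}

#' Transform skewed profile variables towards normality
#'
#' Profile applicabilities are typically positively skewed; PCA loadings are
#' easier to interpret after normalization. Each column gets `log(x + 1)`,
#' `sqrt(x)`, or no transform. Explicit per-column overrides always win;
#' otherwise a skewness rule applies: sample skewness > 1.5 -> log,
#' in (0, 1.5] -> sqrt, else none.
#'
#' @param m Numeric matrix with non-negative values.
#' @param overrides Named character vector, values in
#'   `c("log", "sqrt", "none")`.
#' @return Transformed matrix with attribute `transform_log` (data frame:
#'   column, transform, skewness).
#' @export
transform_for_normality <- function(m, overrides = NULL) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative values: sqrt/log transforms undefined",
                       call. = FALSE)
  cols <- colnames(m)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), cols)
    if (length(bad) > 0L) {
      stop(sprintf("transform override(s) for unknown column(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    stopifnot(all(overrides %in% c("log", "sqrt", "none")))
  }
  sk <- apply(m, 2, e1071::skewness)
  choice <- ifelse(is.na(sk), "none",
                   ifelse(sk > 1.5, "log", ifelse(sk > 0, "sqrt", "none")))
  names(choice) <- cols
  if (!is.null(overrides)) choice[names(overrides)] <- overrides
  out <- m
  for (j in cols) {
    out[, j] <- switch(choice[[j]],
                       log = log(m[, j] + 1),
                       sqrt = sqrt(m[, j]),
                       none = m[, j])
  }
  attr(out, "transform_log") <- data.frame(
    column = cols, transform = unname(choice),
    skewness = unname(sk), stringsAsFactors = FALSE)
  out
}

# Orient a loading vector: tones given -> non-negative loading-tone
# correlation; else the largest-magnitude loading is positive.
.orient_sign <- function(loading, tones = NULL) {
  if (!is.null(tones)) {
    r <- suppressWarnings(stats::cor(loading, tones))
    if (is.finite(r) && r < 0) return(-1)
    if (is.finite(r)) return(1)
  }
  if (loading[which.max(abs(loading))] < 0) -1 else 1
}

#' Principal component analysis of a profile matrix
#'
#' Standard PCA by singular value decomposition of the (usually autoscaled)
#' matrix. Eigenvalues are score variances with divisor n - 1, so on
#' autoscaled data they sum to the number of variables. Component signs are
#' arbitrary in the eigenproblem; here PC1 is oriented so that its loadings
#' correlate non-negatively with the descriptor hedonic tones when these are
#' supplied (larger scores then always mean "more pleasant"), and every
#' remaining component so that its largest-magnitude loading is positive.
#'
#' @param m Numeric matrix (odorants x descriptors), typically from
#'   [autoscale()].
#' @param n_components Number of components to retain.
#' @param tones Optional [hedonic_vocabulary()] or named numeric vector used
#'   to orient PC1.
#' @return List of class `pca_result`: `loadings` (descriptors x components),
#'   `scores` (odorants x components), `eigenvalues`,
#'   `explained_variance` (fractions), `n`, `transform_log` (carried over
#'   from `m` when present).
#' @export
run_pca <- function(m, n_components = min(dim(m) - c(1L, 0L)), tones = NULL) {
  m <- as.matrix(m)
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (n_components > kmax) {
    stop(sprintf("n_components = %d exceeds min(rows - 1, cols) = %d",
                 n_components, kmax), call. = FALSE)
  }
  cm <- colMeans(m)
  mc <- sweep(m, 2, cm)
  sv <- svd(mc, nu = n_components, nv = n_components)
  lambda_all <- sv$d^2 / (nrow(m) - 1)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  tone_vec <- NULL
  if (!is.null(tones)) {
    tone_vec <- if (inherits(tones, "hedonic_vocabulary") || !is.null(names(tones))) {
      unname(tones[canonical_descriptor(colnames(m))])
    } else as.numeric(tones)
  }
  for (k in seq_len(n_components)) {
    s <- .orient_sign(loadings[, k], if (k == 1L) tone_vec else NULL)
    loadings[, k] <- s * loadings[, k]
    scores[, k] <- s * scores[, k]
  }
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(n_components)))
  structure(list(
    loadings = loadings,
    scores = scores,
    eigenvalues = lambda_all[seq_len(n_components)],
    explained_variance = lambda_all[seq_len(n_components)] / sum(lambda_all),
    n = nrow(m),
    transform_log = attr(m, "transform_log")
  ), class = "pca_result")
}

# Rank-k reconstruction of a matrix with missing cells by iterative SVD
# imputation (EM-style): missing entries start at 0 (column mean of
# autoscaled data) and are refined with the rank-k model until convergence.
.svd_impute <- function(m, k, max_iter = 200, tol = 1e-8) {
  miss <- is.na(m)
  x <- m
  x[miss] <- 0
  prev <- x[miss]
  for (it in seq_len(max_iter)) {
    sv <- svd(x, nu = k, nv = k)
    recon <- sv$u %*% diag(sv$d[seq_len(k)], k) %*% t(sv$v)
    x[miss] <- recon[miss]
    if (sqrt(mean((x[miss] - prev)^2)) < tol) break
    prev <- x[miss]
  }
  sv <- svd(x, nu = k, nv = k)
  sv$u %*% diag(sv$d[seq_len(k)], k) %*% t(sv$v)
}

#' Cross-validated Q2 per principal component
#'
#' Component-retention criterion: a component is worth keeping if it
#' predicts data it was not fitted on. Cells of the matrix are assigned at
#' random to `folds` groups (element-wise deletion); each group in turn is
#' held out, the rank-k model is re-estimated from the remaining cells by
#' iterative SVD imputation, and the held-out cells are predicted. With
#' `PRESS_k` the held-out squared error of the rank-k model and `SS_(k-1)`
#' the residual sum of squares after k - 1 components on the full data,
#' `Q2_k = 1 - PRESS_k / SS_(k-1)`. Values are at most 1; negative values
#' mean the component predicts worse than no component.
#'
#' @param m Numeric matrix, typically autoscaled.
#' @param n_components Components to evaluate.
#' @param folds Number of deletion groups (>= 2).
#' @param seed Integer seed for the random cell assignment.
#' @return Numeric vector of per-component Q2 values.
#' @export
q2_cross_validation <- function(m, n_components = 2L, folds = 7L, seed) {
  m <- as.matrix(m)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (folds > nrow(m)) stop("more folds than rows", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  assign <- matrix(sample(rep_len(seq_len(folds), length(m))),
                   nrow(m), ncol(m))
  cm <- colMeans(m)
  mc <- sweep(m, 2, cm)
  press <- numeric(n_components)
  for (f in seq_len(folds)) {
    hold <- assign == f
    mtrain <- mc
    mtrain[hold] <- NA
    for (k in seq_len(n_components)) {
      recon <- .svd_impute(mtrain, k)
      press[k] <- press[k] + sum((mc[hold] - recon[hold])^2)
    }
  }
  sv <- svd(mc)
  ss_resid <- numeric(n_components)
  ss_resid[1] <- sum(mc^2)
  if (n_components > 1L) {
    for (k in 2:n_components) {
      ss_resid[k] <- sum(sv$d[k:length(sv$d)]^2)
    }
  }
  1 - press / ss_resid
}

#' No-intercept quadratic fit of PC1 loadings on hedonic tones
#'
#' Fits `p1 = b1 * HT + b2 * HT^2` through the origin, so descriptors with
#' positive loadings map to positive fitted tones wherever the parabola is
#' increasing. Reports R-squared through the origin and flags descriptors
#' with |studentized residual| > 2 as outliers.
#'
#' @param p1 Numeric PC1 loadings (named by descriptor, optionally).
#' @param tones Numeric hedonic tones, same length.
#' @return List of class `loading_tone_model`: `coefficients` (linear,
#'   quadratic), `r_squared`, `residuals`, `outliers` (names or indices).
#' @export
fit_loading_tone_quadratic <- function(p1, tones) {
  stopifnot(length(p1) == length(tones))
  if (length(p1) < 3L) stop("need at least 3 descriptor pairs", call. = FALSE)
  tones <- as.numeric(tones)
  if (all(tones == 0)) stop("singular design: all tones are zero", call. = FALSE)
  d <- data.frame(p = as.numeric(p1), ht = tones)
  fit <- stats::lm(p ~ 0 + ht + I(ht^2), data = d)
  res <- stats::residuals(fit)
  stud <- stats::rstudent(fit)
  out_idx <- which(abs(stud) > 2)
  nm <- if (!is.null(names(p1))) names(p1) else as.character(seq_along(p1))
  structure(list(
    coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                   c("linear", "quadratic")),
    r_squared = 1 - sum(res^2) / sum(d$p^2),
    residuals = stats::setNames(res, nm),
    studentized = stats::setNames(stud, nm),
    outliers = nm[out_idx],
    fit = fit
  ), class = "loading_tone_model")
}

#' Decide whether PC1 of a profile matrix is the hedonic dimension
#'
#' Combines the evidence used when a profile PCA is read by eye: (a) the
#' Pearson correlation (with two-sided p-value) between PC1 loadings and the
#' descriptor hedonic tones, (b) the correlation between PC1 scores and the
#' weighted-average hedonic estimates when supplied, (c) the eigenvalue > 1
#' retention criterion and the cross-validated Q2 threshold. The default
#' combined rule calls PC1 hedonic when the loading-tone correlation is
#' positive and significant at `alpha` and at least one retention criterion
#' holds; pass `rule` to change it.
#'
#' @param pca A [run_pca()] result.
#' @param tones [hedonic_vocabulary()] or named numeric vector covering every
#'   descriptor of the loadings.
#' @param eq1_scores Optional data frame from [estimate_hedonic_eq1()] (or
#'   numeric vector aligned with score rows) for the score-score correlation.
#' @param q2 Optional Q2 vector from [q2_cross_validation()].
#' @param q2_threshold Q2 retention threshold for PC1 (default 0.13, the
#'   conventional small-matrix value; configure per dataset).
#' @param alpha Significance level for the loading-tone test.
#' @param rule Function of the report list returning the combined verdict.
#' @return List of class `hedonic_decision`.
#' @export
hedonic_decision <- function(pca, tones, eq1_scores = NULL, q2 = NULL,
                             q2_threshold = 0.13, alpha = 0.05, rule = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  desc <- rownames(pca$loadings)
  tone_vec <- if (!is.null(names(tones))) {
    miss <- setdiff(canonical_descriptor(desc), names(tones))
    if (length(miss) > 0L) {
      stop(sprintf("no tone for descriptor(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    unname(tones[canonical_descriptor(desc)])
  } else {
    stopifnot(length(tones) == length(desc))
    as.numeric(tones)
  }
  ct <- stats::cor.test(pca$loadings[, 1], tone_vec)
  score_cor <- NULL
  if (!is.null(eq1_scores)) {
    s <- if (is.data.frame(eq1_scores)) {
      stats::setNames(eq1_scores$hedonic_score, eq1_scores$id)[rownames(pca$scores)]
    } else as.numeric(eq1_scores)
    ok <- is.finite(s)
    score_cor <- stats::cor.test(pca$scores[ok, 1], s[ok])
  }
  report <- list(
    loading_tone_r = unname(ct$estimate),
    loading_tone_p = ct$p.value,
    score_eq1_r = if (!is.null(score_cor)) unname(score_cor$estimate) else NA_real_,
    score_eq1_p = if (!is.null(score_cor)) score_cor$p.value else NA_real_,
    eigenvalue_pc1 = pca$eigenvalues[1],
    eigenvalue_criterion = pca$eigenvalues[1] > 1,
    q2_pc1 = if (!is.null(q2)) q2[1] else NA_real_,
    q2_criterion = if (!is.null(q2)) q2[1] > q2_threshold else NA,
    q2_threshold = q2_threshold,
    alpha = alpha
  )
  if (is.null(rule)) {
    rule <- function(rep) {
      assoc <- is.finite(rep$loading_tone_r) && rep$loading_tone_r > 0 &&
        rep$loading_tone_p < rep$alpha
      retain <- isTRUE(rep$eigenvalue_criterion) || isTRUE(rep$q2_criterion)
      assoc && retain
    }
  }
  report$is_pc1_hedonic <- rule(report)
  structure(report, class = "hedonic_decision")
}

#' @export
print.hedonic_decision <- function(x, ...) {
  cat("PC1 hedonic-dimension decision\n")
  cat(sprintf("  loading-tone r = %.3f (p = %.4g)\n",
              x$loading_tone_r, x$loading_tone_p))
  if (is.finite(x$score_eq1_r)) {
    cat(sprintf("  score vs weighted-average r = %.3f (p = %.4g)\n",
                x$score_eq1_r, x$score_eq1_p))
  }
  cat(sprintf("  eigenvalue(PC1) = %.3f (> 1: %s)\n", x$eigenvalue_pc1,
              x$eigenvalue_criterion))
  if (is.finite(x$q2_pc1)) {
    cat(sprintf("  Q2(PC1) = %.3f (> %.2f: %s)\n", x$q2_pc1, x$q2_threshold,
                x$q2_criterion))
  }
  cat(sprintf("  verdict: PC1 %s the hedonic dimension\n",
              if (x$is_pc1_hedonic) "IS" else "is NOT"))
  invisible(x)
}
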