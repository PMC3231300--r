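# Hedonic-score ~ molecular-feature regressions: published preset equations,
# OLS fitting with diagnostics, and analytic properties of the fitted
# polynomials in molecular size (pleasantness thresholds, hedonic optima).

# Recognised regression terms. n_at_sq is the quadratic size term, i_ox_nat
# the oxygen x size interaction.
.model_terms <- c("(Intercept)", "n_at", "n_at_sq", "i_ox", "i_sul",
                  "i_acid", "i_amine", "i_ox_nat")

.new_model <- function(coefficients, provenance, scale = "H", se = NULL,
                       p_values = NULL, r_squared = NA_real_, n = NA_integer_,
                       diagnostics = NULL, advisory = NULL) {
  stopifnot(all(names(coefficients) %in% .model_terms))
  structure(list(coefficients = coefficients, provenance = provenance,
                 scale = scale, se = se, p_values = p_values,
                 r_squared = r_squared, n = n, diagnostics = diagnostics,
                 advisory = advisory),
            class = "hedonic_model")
}

#' Registry of published hedonic prediction equations
#'
#' Immutable presets on the -4..+4 hedonic scale, fitted in the source
#' studies to five chemical sets. Coefficients are the printed values:
#' \describe{
#'   \item{eq7}{`-2.56 + 0.23 n_at + 1.26 i_ox - 1.54 i_sul`}
#'   \item{eq8}{preference-ranking scale:
#'     `106.9 - 2.49 n_at - 17.33 i_ox + 21.6 i_sul + 28.32 i_acid + 20.77 i_amine`}
#'   \item{eq9}{`-2.62 + 0.23 n_at + 1.58 i_ox - 1.96 i_sul - 2.58 i_acid - 1.89 i_amine`}
#'   \item{eq10}{`-1.87 + 0.22 n_at + 2.60 i_ox - 2.23 i_sul - 3.51 i_acid`;
#'     carries a "not recommended for prediction" advisory (fitted on a set
#'     with no neutral odorants)}
#'   \item{eq11}{`-2.33 + 0.33 n_at - 0.0104 n_at^2 + 0.057 i_ox*n_at - 0.83 i_sul - 1.62 i_acid`}
#'   \item{eq12}{`-1.85 + 0.35 n_at - 0.014 n_at^2 + 0.041 i_ox*n_at`}
#' }
#'
#' @return Named list of `hedonic_model` objects.
#' @export
preset_equations <- function() {
  list(
    eq7 = .new_model(
      c("(Intercept)" = -2.56, n_at = 0.23, i_ox = 1.26, i_sul = -1.54),
      provenance = "preset:eq7", r_squared = 0.537, n = 51L),
    eq8 = .new_model(
      c("(Intercept)" = 106.9, n_at = -2.49, i_ox = -17.33, i_sul = 21.6,
        i_acid = 28.32, i_amine = 20.77),
      provenance = "preset:eq8", scale = "PR", r_squared = 0.707, n = 61L,
      advisory = "preference-ranking scale; convert via the eq3 calibration"),
    eq9 = .new_model(
      c("(Intercept)" = -2.62, n_at = 0.23, i_ox = 1.58, i_sul = -1.96,
        i_acid = -2.58, i_amine = -1.89),
      provenance = "preset:eq9", r_squared = 0.707, n = 61L),
    eq10 = .new_model(
      c("(Intercept)" = -1.87, n_at = 0.22, i_ox = 2.60, i_sul = -2.23,
        i_acid = -3.51),
      provenance = "preset:eq10", r_squared = 0.711, n = 45L,
      advisory = "not recommended for prediction"),
    eq11 = .new_model(
      c("(Intercept)" = -2.33, n_at = 0.33, n_at_sq = -0.0104,
        i_ox_nat = 0.057, i_sul = -0.83, i_acid = -1.62),
      provenance = "preset:eq11", r_squared = 0.503, n = 142L),
    eq12 = .new_model(
      c("(Intercept)" = -1.85, n_at = 0.35, n_at_sq = -0.014,
        i_ox_nat = 0.041),
      provenance = "preset:eq12", r_squared = 0.458, n = 107L)
  )
}

#' Published calibration constants between hedonic-score variants
#'
#' Affine/quadratic relations linking hedonic scores obtained by different
#' routes: `eq2` panel ratings vs profile-weighted estimates (intercept,
#' slope); `eq3` panel ratings vs preference rankings; `eq5` PCA scores vs
#' weighted estimates (intercept, linear, quadratic); `eq6` panel ratings vs
#' Atlas weighted estimates.
#'
#' @return Named list of numeric coefficient vectors.
#' @export
calibration_constants <- function() {
  list(eq2 = c(0.26, 1.03), eq3 = c(7.11, -0.091),
       eq5 = c(-0.297, 3.365, -0.491), eq6 = c(0.185, 1.228))
}

# Resolve a model argument: either a hedonic_model or a preset id string.
resolve_model <- function(model) {
  if (inherits(model, "hedonic_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    reg <- preset_equations()
    if (model %in% names(reg)) return(reg[[model]])
    stop(sprintf("unknown preset equation '%s' (have: %s)", model,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  stop("model must be a hedonic_model or a preset id", call. = FALSE)
}

# Build the design matrix for a term list from a feature table.
# Refuses NA (undetermined) indicators for terms that need them.
build_design <- function(features, terms) {
  terms <- match.arg(terms, .model_terms, several.ok = TRUE)
  cols <- lapply(terms, function(tm) {
    switch(tm,
      "(Intercept)" = rep(1, nrow(features)),
      n_at = features$n_at,
      n_at_sq = features$n_at^2,
      i_ox = features$i_ox,
      i_sul = features$i_sul,
      i_acid = features$i_acid,
      i_amine = features$i_amine,
      i_ox_nat = features$i_ox * features$n_at)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  na_cols <- terms[colSums(is.na(X)) > 0]
  if (length(na_cols) > 0L) {
    stop(sprintf(
      "undetermined feature value(s) for term(s): %s (formula-only molecules without explicit acid/amine flags?)",
      paste(na_cols, collapse = ", ")), call. = FALSE)
  }
  X
}

#' Fit a hedonic-score regression on molecular features
#'
#' Ordinary least squares of hedonic scores on a user-chosen subset of
#' `{1, n_at, n_at^2, i_ox, i_sul, i_acid, i_amine, i_ox*n_at}`, with the
#' diagnostics used when such models are screened by hand: per-term standard
#' errors and p-values, a residual-normality test (Shapiro-Wilk), and an
#' influential-point report (Cook's distance > 1 or leverage > 3p/n).
#' Influential points are only excluded on explicit opt-in
#' (`exclude = "influential"` or a vector of ids), so any exclusion is
#' auditable.
#'
#' @param features Feature data frame ([featurize_table()] or the synthetic
#'   generator's truth table): columns `id`, `n_at`, `i_ox`, `i_sul`,
#'   `i_acid`, `i_amine`.
#' @param scores Score data frame with columns `id`, `hedonic_score` (rows
#'   with non-finite scores are dropped), or a numeric vector aligned with
#'   `features`.
#' @param terms Character vector of term names; include `"(Intercept)"`
#'   explicitly.
#' @param exclude `"none"` (default), `"influential"`, or a character vector
#'   of ids to drop before fitting.
#' @return A `hedonic_model` with `provenance = "fitted"`.
#' @export
fit_hedonic_model <- function(features, scores,
                              terms = c("(Intercept)", "n_at", "i_ox", "i_sul"),
                              exclude = "none") {
  if (is.data.frame(scores)) {
    merged <- merge(features, scores[, c("id", "hedonic_score")], by = "id")
  } else {
    stopifnot(length(scores) == nrow(features))
    merged <- features
    merged$hedonic_score <- as.numeric(scores)
  }
  merged <- merged[is.finite(merged$hedonic_score), , drop = FALSE]
  if (is.character(exclude) && length(exclude) >= 1L && !identical(exclude, "none") &&
      !identical(exclude, "influential")) {
    merged <- merged[!merged$id %in% exclude, , drop = FALSE]
  }
  X <- build_design(merged, terms)
  if (nrow(X) <= ncol(X)) {
    stop("not enough observations for the requested terms", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop(sprintf("collinear design: terms %s are linearly dependent",
                 paste(terms, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm.fit(X, merged$hedonic_score)
  fitted_lm <- stats::lm(merged$hedonic_score ~ 0 + X)
  sm <- suppressWarnings(summary(fitted_lm))  # noiseless data is legitimate
  coefs <- stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
  se <- stats::setNames(sm$coefficients[, "Std. Error"], colnames(X))
  pv <- stats::setNames(sm$coefficients[, "Pr(>|t|)"], colnames(X))
  res <- stats::residuals(fitted_lm)
  r2 <- if ("(Intercept)" %in% terms) {
    1 - sum(res^2) / sum((merged$hedonic_score - mean(merged$hedonic_score))^2)
  } else {
    1 - sum(res^2) / sum(merged$hedonic_score^2)
  }
  h <- stats::hatvalues(fitted_lm)
  cd <- stats::cooks.distance(fitted_lm)
  infl <- cd > 1 | h > 3 * ncol(X) / nrow(X)
  infl[is.na(infl)] <- FALSE
  shap <- if (nrow(X) >= 3 && nrow(X) <= 5000 && stats::sd(res) > 0) {
    stats::shapiro.test(res)
  } else NULL
  diagnostics <- list(
    residual_normality = if (!is.null(shap)) {
      c(statistic = unname(shap$statistic), p_value = unname(shap$p.value))
    } else NULL,
    influential = data.frame(id = merged$id[infl],
                             cooks_distance = unname(cd[infl]),
                             leverage = unname(h[infl]),
                             stringsAsFactors = FALSE),
    residuals = stats::setNames(res, merged$id)
  )
  model <- .new_model(coefs, provenance = "fitted", se = se, p_values = pv,
                      r_squared = r2, n = nrow(X), diagnostics = diagnostics)
  if (identical(exclude, "influential") && nrow(diagnostics$influential) > 0L) {
    model <- fit_hedonic_model(features, scores, terms,
                               exclude = diagnostics$influential$id)
    model$diagnostics$excluded <- diagnostics$influential$id
  }
  model
}

#' Predict hedonic scores from a model or preset
#'
#' @param model A `hedonic_model` or a preset id (`"eq7"`, `"eq9"`, `"eq10"`,
#'   `"eq11"`, `"eq12"`).
#' @param features Feature data frame (columns `id`, `n_at`, indicators).
#' @return Data frame `id`, `hedonic_score`, `method` (`"regression"`),
#'   `flags`.
#' @examples
#' f <- data.frame(id = "x", n_at = 10, i_ox = 1, i_sul = 0,
#'                 i_acid = 0, i_amine = 0)
#' predict_hedonic("eq7", f)  # -2.56 + 2.30 + 1.26 = 1.00
#' @export
predict_hedonic <- function(model, features) {
  model <- resolve_model(model)
  X <- build_design(features, names(model$coefficients))
  flags <- if (is.null(model$advisory)) "" else model$advisory
  data.frame(id = features$id,
             hedonic_score = as.numeric(X %*% model$coefficients),
             method = "regression",
             flags = flags,
             stringsAsFactors = FALSE)
}

# Collapse a model to a polynomial in n_at for a fixed indicator pattern:
# returns c(c0, c1, c2) of c0 + c1*x + c2*x^2.
.nat_polynomial <- function(model, i_ox = 1, i_sul = 0, i_acid = 0,
                            i_amine = 0) {
  cf <- model$coefficients
  g <- function(tm) if (tm %in% names(cf)) unname(cf[tm]) else 0
  c0 <- g("(Intercept)") + i_ox * g("i_ox") + i_sul * g("i_sul") +
    i_acid * g("i_acid") + i_amine * g("i_amine")
  c1 <- g("n_at") + i_ox * g("i_ox_nat")
  c2 <- g("n_at_sq")
  c(c0, c1, c2)
}

#' Pleasantness threshold: molecular size at which a model crosses zero
#'
#' Holding the indicator pattern fixed (default: an oxygenated molecule with
#' no sulfur, acid or amine group), the prediction is a polynomial in the
#' heavy-atom count. Its real roots in (0, 100) are returned in ascending
#' order; for quadratics, the smaller positive root is the pleasantness
#' threshold and the larger one - typically beyond the fitted size range -
#' is flagged as extrapolation.
#'
#' @param model `hedonic_model` or preset id.
#' @param i_ox,i_sul,i_acid,i_amine Fixed indicator pattern.
#' @return List: `roots` (ascending, within (0, 100)), `threshold` (smaller
#'   positive root or `NA`), `crossing` (logical), `extrapolation_flag`
#'   (larger quadratic root, when present).
#' @examples
#' null_crossing("eq7")$threshold  # (2.56 - 1.26) / 0.23 = 5.652
#' @export
null_crossing <- function(model, i_ox = 1, i_sul = 0, i_acid = 0,
                          i_amine = 0) {
  model <- resolve_model(model)
  if (!"n_at" %in% names(model$coefficients)) {
    stop("model has no n_at term", call. = FALSE)
  }
  pol <- .nat_polynomial(model, i_ox, i_sul, i_acid, i_amine)
  roots <- if (pol[3] != 0) {
    disc <- pol[2]^2 - 4 * pol[3] * pol[1]
    if (disc < 0) numeric(0) else {
      sort((-pol[2] + c(-1, 1) * sqrt(disc)) / (2 * pol[3]))
    }
  } else if (pol[2] != 0) {
    -pol[1] / pol[2]
  } else {
    numeric(0)
  }
  roots <- roots[roots > 0 & roots < 100]
  list(
    roots = roots,
    threshold = if (length(roots) > 0) roots[1] else NA_real_,
    crossing = length(roots) > 0,
    extrapolation_flag = if (pol[3] != 0 && length(roots) == 2) roots[2] else NULL
  )
}

#' Hedonic optimum in molecular size
#'
#' For models with a negative quadratic size term, the prediction (at a fixed
#' indicator pattern) peaks at the parabola vertex; the vertex location and
#' the maximal score are returned. Models without a quadratic term are
#' monotone in size; a positive quadratic coefficient makes the prediction
#' unbounded.
#'
#' @inheritParams null_crossing
#' @return List: `kind` (`"optimum"`, `"monotone"`, or `"unbounded"`),
#'   `nat_opt`, `max_score`.
#' @examples
#' optimum_nat("eq12")$nat_opt  # (0.35 + 0.041) / (2 * 0.014) = 13.96
#' @export
optimum_nat <- function(model, i_ox = 1, i_sul = 0, i_acid = 0, i_amine = 0) {
  model <- resolve_model(model)
  pol <- .nat_polynomial(model, i_ox, i_sul, i_acid, i_amine)
  if (pol[3] == 0) {
    return(list(kind = "monotone", nat_opt = NA_real_, max_score = NA_real_))
  }
  if (pol[3] > 0) {
    return(list(kind = "unbounded", nat_opt = NA_real_, max_score = NA_real_))
  }
  v <- -pol[2] / (2 * pol[3])
  list(kind = "optimum", nat_opt = v,
       max_score = pol[1] + pol[2] * v + pol[3] * v^2)
}

#' Classify scores as pleasant and report the pleasant fraction
#'
#' Pleasant means a strictly positive hedonic score; zero is not pleasant.
#'
#' @param scores Numeric vector or a score data frame with `hedonic_score`.
#' @return List: `classes` (logical vector), `fraction_pleasant`, `n`.
#' @export
classify_pleasant <- function(scores) {
  x <- if (is.data.frame(scores)) scores$hedonic_score else as.numeric(scores)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite scores to classify", call. = FALSE)
  cls <- x > 0
  list(classes = cls, fraction_pleasant = mean(cls), n = length(x))
}

#' Compare two hedonic-score sets
#'
#' Pearson correlation with its two-sided p-value (t transform, n - 2 df)
#' plus the least-squares line of `b` on `a` with 95% confidence intervals
#' on intercept and slope.
#'
#' @param a,b Paired numeric scores; non-finite pairs dropped.
#' @return List: `r`, `p_value`, `intercept`, `slope`, `conf_int` (2x2),
#'   `n`.
#' @export
compare_scores <- function(a, b) {
  if (is.data.frame(a)) a <- a$hedonic_score
  if (is.data.frame(b)) b <- b$hedonic_score
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 paired scores", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in one of the score sets", call. = FALSE)
  }
  ct <- stats::cor.test(a, b)
  fit <- stats::lm(b ~ a)
  ci <- suppressWarnings(stats::confint(fit))  # exact fits are legitimate
  list(r = unname(ct$estimate), p_value = ct$p.value,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       conf_int = ci, n = length(a))
}

#' @export
print.hedonic_model <- function(x, ...) {
  cat(sprintf("Hedonic regression model [%s] on the %s scale\n",
              x$provenance, if (x$scale == "H") "-4..+4 hedonic" else
                "preference-ranking"))
  tab <- data.frame(coefficient = x$coefficients)
  if (!is.null(x$se)) tab$se <- x$se
  if (!is.null(x$p_values)) tab$p_value <- signif(x$p_values, 3)
  print(tab)
  if (is.finite(x$r_squared)) cat(sprintf("R-squared: %.3f  (n = %d)\n",
                                          x$r_squared, x$n))
  if (!is.null(x$advisory)) cat("Advisory:", x$advisory, "\n")
  if (!is.null(x$diagnostics) && nrow(x$diagnostics$influential) > 0L) {
    cat("Influential points:",
        paste(x$diagnostics$influential$id, collapse = ", "), "\n")
  }
  invisible(x)
}
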