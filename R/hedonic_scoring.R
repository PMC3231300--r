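# Hedonic-tone vocabularies, odor-profile matrices, and the weighted-average
# hedonic estimator on the -4..+4 valence scale.

#' The seven-point semantic hedonic scale
#'
#' Symmetric coding of verbal hedonic labels onto the -4..+4 valence scale,
#' with the intermediate steps at the conventionally printed two-decimal
#' values (-2.67, -1.33, 1.33, 2.67).
#'
#' @return Named numeric vector, ordered from very unpleasant to very
#'   pleasant.
#' @export
semantic_hedonic_scale <- function() {
  c("very unpleasant" = -4, "moderately unpleasant" = -2.67,
    "slightly unpleasant" = -1.33, "neutral" = 0,
    "slightly pleasant" = 1.33, "moderately pleasant" = 2.67,
    "very pleasant" = 4)
}

# Descriptor / label canonicalization: case-fold, trim, collapse internal
# whitespace. Comma-variants like "sour, vinegar" stay verbatim as names.
canonical_descriptor <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Code a semantic hedonic label to its numeric value
#'
#' @param label One of the seven labels of [semantic_hedonic_scale()]
#'   (case- and whitespace-insensitive).
#' @return Numeric hedonic value on the -4..+4 scale.
#' @examples
#' code_semantic_hedonic("moderately unpleasant")  # -2.67
#' @export
code_semantic_hedonic <- function(label) {
  scale <- semantic_hedonic_scale()
  key <- canonical_descriptor(label)
  bad <- !key %in% names(scale)
  if (any(bad)) {
    stop(sprintf("unknown semantic hedonic label(s): %s",
                 paste(unique(label[bad]), collapse = ", ")), call. = FALSE)
  }
  unname(scale[key])
}

#' Construct a hedonic-tone vocabulary
#'
#' A vocabulary maps odor-character descriptors to hedonic tones on the
#' -4..+4 scale (panel-rated pleasantness of the descriptor itself).
#' Descriptor names are canonicalized (case-folded, trimmed, internal
#' whitespace collapsed) and must be unique afterwards.
#'
#' @param descriptors Character vector of descriptor names.
#' @param tones Numeric tones, each in `[-4, 4]`.
#' @param provenance Free-text provenance label.
#' @return Named numeric vector of class `hedonic_vocabulary`.
#' @export
hedonic_vocabulary <- function(descriptors, tones, provenance = "user") {
  stopifnot(length(descriptors) == length(tones), length(tones) > 0L)
  tones <- as.numeric(tones)
  if (any(!is.finite(tones)) || any(tones < -4 | tones > 4)) {
    stop("hedonic tones must be finite and within [-4, 4]", call. = FALSE)
  }
  nm <- canonical_descriptor(descriptors)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate descriptor(s) after canonicalization: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(stats::setNames(tones, nm), class = "hedonic_vocabulary",
            provenance = provenance)
}

#' Read a hedonic-tone vocabulary from delimited text
#'
#' @param path File with header columns `descriptor`, `hedonic_tone`.
#' @param sep Field separator.
#' @return A [hedonic_vocabulary()].
#' @export
read_vocabulary <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("descriptor", "hedonic_tone") %in% names(df))) {
    stop("vocabulary file needs columns 'descriptor' and 'hedonic_tone'",
         call. = FALSE)
  }
  hedonic_vocabulary(df$descriptor, df$hedonic_tone, provenance = path)
}

#' Published hedonic tones for a handful of descriptors
#'
#' The subset of the 146-descriptor panel vocabulary (tones rated by a panel
#' of about 120 subjects on the -4..+4 scale) whose values are public:
#' fruity 2.23, sweet 2.03, sulfidic -2.45, "sour, vinegar" -1.26,
#' "sharp, pungent, acid" -2.34, ammonia -2.47, fishy -1.98, urinous -3.34.
#' The full vocabulary is not redistributable and must be supplied by the
#' user via [read_vocabulary()].
#'
#' @return A [hedonic_vocabulary()].
#' @export
ht_d84_printed <- function() {
  path <- system.file("extdata", "ht_d84_printed.csv", package = "odorhedonics",
                      mustWork = TRUE)
  read_vocabulary(path)
}

#' Construct an odor-profile matrix
#'
#' Rows are odorants, columns are odor-character descriptors; entries are
#' non-negative applicability values (percentage scale 0-100, or raw
#' similarity ratings).
#'
#' @param x Numeric matrix with row and column names.
#' @return Matrix of class `odor_profile`.
#' @export
odor_profile_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("profile values must be numeric", call. = FALSE)
  if (is.null(colnames(x)) || (nrow(x) > 0L && is.null(rownames(x)))) {
    stop("profile matrix needs odorant row names and descriptor column names",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("profile values must be finite and non-negative", call. = FALSE)
  }
  colnames(x) <- canonical_descriptor(colnames(x))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("duplicate row or column labels in profile matrix", call. = FALSE)
  }
  class(x) <- c("odor_profile", class(x))
  x
}

#' Read an odor-profile matrix from delimited text
#'
#' First column is the odorant id; remaining columns are descriptors.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return An [odor_profile_matrix()].
#' @export
read_profile_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  odor_profile_matrix(m)
}

#' Zero out sub-threshold applicabilities and drop empty descriptors
#'
#' Applicability values below 4% of the scale maximum are indistinguishable
#' from panel noise; they are set to zero (strictly below the threshold -
#' values exactly at it are kept). Descriptor columns that become all-zero
#' are removed and recorded in the `dropped_columns` attribute.
#'
#' @param m An [odor_profile_matrix()].
#' @param threshold Noise threshold (default 4).
#' @return Cleaned `odor_profile` with attribute `dropped_columns`.
#' @export
clean_profile <- function(m, threshold = 4) {
  stopifnot(inherits(m, "odor_profile"), threshold >= 0)
  m[m < threshold] <- 0
  dead <- colnames(m)[colSums(m) == 0]
  out <- unclass(m)[, colSums(m) > 0, drop = FALSE]
  if (ncol(out) == 0L) stop("all descriptor columns are empty after thresholding",
                            call. = FALSE)
  out <- odor_profile_matrix(out)
  attr(out, "dropped_columns") <- dead
  out
}

#' Rename, merge and drop descriptor columns
#'
#' Aliases map profile descriptors onto vocabulary descriptors (e.g.
#' wintergreen -> medicinal). If the alias target column already exists the
#' two are merged by element-wise maximum, keeping applicability on the 0-100
#' scale. Descriptors in `drop` are removed.
#'
#' @param m An [odor_profile_matrix()].
#' @param aliases Named character vector `c(from = to, ...)`.
#' @param drop Character vector of descriptors to remove.
#' @param vocabulary Optional [hedonic_vocabulary()]; when given, alias
#'   targets must exist in it.
#' @return `odor_profile` with attribute `alias_log`.
#' @export
apply_descriptor_aliases <- function(m, aliases = NULL, drop = character(0),
                                     vocabulary = NULL) {
  stopifnot(inherits(m, "odor_profile"))
  log <- character(0)
  drop <- canonical_descriptor(drop)
  keep <- !(colnames(m) %in% drop)
  if (any(!keep)) log <- c(log, paste("dropped:", colnames(m)[!keep]))
  m2 <- m[, keep, drop = FALSE]
  if (!is.null(aliases) && length(aliases) > 0L) {
    from <- canonical_descriptor(names(aliases))
    to <- canonical_descriptor(unname(aliases))
    if (!is.null(vocabulary)) {
      missing <- setdiff(to, names(vocabulary))
      if (length(missing) > 0L) {
        stop(sprintf("alias target(s) not in vocabulary: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
    }
    for (k in seq_along(from)) {
      if (!from[k] %in% colnames(m2)) next
      if (to[k] %in% colnames(m2)) {
        m2[, to[k]] <- pmax(m2[, to[k]], m2[, from[k]])
        m2 <- m2[, colnames(m2) != from[k], drop = FALSE]
        log <- c(log, sprintf("merged: %s -> %s (element-wise max)",
                              from[k], to[k]))
      } else {
        colnames(m2)[colnames(m2) == from[k]] <- to[k]
        log <- c(log, sprintf("renamed: %s -> %s", from[k], to[k]))
      }
    }
  }
  out <- odor_profile_matrix(unclass(m2))
  attr(out, "alias_log") <- log
  out
}

#' Estimate hedonic scores as the tone-weighted average of a profile
#'
#' For odorant i with applicabilities x_ij and descriptor tones HT_j, the
#' hedonic score is `H_i = sum_j HT_j * x_ij / sum_j x_ij` - a convex
#' combination of the tones of the descriptors applied to the odorant, hence
#' bounded by their minimum and maximum and invariant to rescaling a profile
#' row. Rows with zero total applicability (odorless samples) yield `NA`
#' flagged `"odorless"`.
#'
#' @param m An [odor_profile_matrix()].
#' @param vocabulary A [hedonic_vocabulary()] covering every column of `m`.
#' @return Data frame `id`, `hedonic_score`, `method` (`"eq1"`), `flags`.
#' @examples
#' m <- odor_profile_matrix(matrix(c(36, 8), 1, 2,
#'   dimnames = list("benzyl acetate", c("fruity", "sweet"))))
#' v <- hedonic_vocabulary(c("fruity", "sweet"), c(2.23, 2.03))
#' estimate_hedonic_eq1(m, v)  # 2.1936
#' @export
estimate_hedonic_eq1 <- function(m, vocabulary) {
  stopifnot(inherits(m, "odor_profile"), inherits(vocabulary, "hedonic_vocabulary"))
  if (ncol(m) < 1L) stop("profile matrix has no descriptor columns", call. = FALSE)
  missing <- setdiff(colnames(m), names(vocabulary))
  if (length(missing) > 0L) {
    stop(sprintf("no hedonic tone for descriptor(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tones <- unname(vocabulary[colnames(m)])
  wsum <- rowSums(m)
  score <- as.numeric(m %*% tones) / wsum
  score[wsum == 0] <- NA_real_
  data.frame(
    id = rownames(m),
    hedonic_score = score,
    method = "eq1",
    flags = ifelse(wsum == 0, "odorless", ""),
    stringsAsFactors = FALSE
  )
}

#' Convert preference rankings to hedonic scores
#'
#' Mean preference rankings (lower = more preferred) are mapped onto the
#' -4..+4 hedonic scale through the published affine calibration
#' `H = 7.11 - 0.091 * PR`, obtained by regressing panel hedonic ratings on
#' rankings for the compounds common to both studies.
#'
#' @param pr Numeric vector of positive preference rankings.
#' @param ids Optional identifiers.
#' @return Data frame `id`, `hedonic_score`, `method` (`"converted-ranking"`),
#'   `flags`.
#' @export
convert_preference_ranking <- function(pr, ids = NULL) {
  pr <- as.numeric(pr)
  if (any(!is.finite(pr)) || any(pr <= 0)) {
    stop("preference rankings must be positive", call. = FALSE)
  }
  cc <- calibration_constants()$eq3
  data.frame(
    id = if (is.null(ids)) as.character(seq_along(pr)) else as.character(ids),
    hedonic_score = cc[1] + cc[2] * pr,
    method = "converted-ranking",
    flags = "",
    stringsAsFactors = FALSE
  )
}

#' Fit an affine or quadratic calibration between two score sets
#'
#' Ordinary least squares of `y` on `x` (and `x^2` when `quadratic`), with or
#' without an intercept; used to compare hedonic scores obtained by different
#' routes (panel ratings vs profile-weighted estimates, weighted estimates vs
#' PCA scores).
#'
#' @param x,y Paired numeric scores; non-finite pairs are dropped.
#' @param with_intercept Include an intercept term.
#' @param quadratic Include an `x^2` term.
#' @return List of class `score_calibration`: `coefficients` (named), `se`,
#'   `p_values`, `r`, `r_squared`, `n`, `fit` (the `lm` object).
#' @export
fit_score_calibration <- function(x, y, with_intercept = TRUE,
                                  quadratic = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n_terms <- 1L + with_intercept + quadratic
  if (length(x) < n_terms + 1L) {
    stop("not enough paired finite observations for calibration", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("singular fit: x is constant", call. = FALSE)
  d <- data.frame(x = x, y = y)
  form <- if (quadratic) {
    if (with_intercept) y ~ x + I(x^2) else y ~ 0 + x + I(x^2)
  } else {
    if (with_intercept) y ~ x else y ~ 0 + x
  }
  fit <- stats::lm(form, data = d)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary() warning
  structure(list(
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    p_values = sm$coefficients[, "Pr(>|t|)"],
    r = stats::cor(x, y),
    r_squared = sm$r.squared,
    n = length(x),
    fit = fit
  ), class = "score_calibration")
}

#' Write a hedonic-score table to delimited text
#'
#' @param scores Data frame as produced by the scoring operations.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_score_table <- function(scores, path, sep = ",") {
  utils::write.table(scores, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
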