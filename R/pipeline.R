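# End-to-end orchestration of the three analyses: profile -> hedonic scores,
# scores + molecules -> regression with analytics, profile -> PCA decision.
# Every run carries a manifest (inputs, seed, package version) so results are
# reproducible.

# Build a run manifest. File inputs are digested; in-memory inputs recorded
# by dimension.
run_manifest <- function(command, inputs = list(), config = list(),
                         seed = NA_integer_) {
  digests <- lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(tools::md5sum(x))
    } else if (is.matrix(x) || is.data.frame(x)) {
      paste0("dim:", paste(dim(x), collapse = "x"))
    } else {
      paste0("length:", length(x))
    }
  })
  list(command = command, inputs = digests, config = config, seed = seed,
       package_version = as.character(utils::packageVersion("odorhedonics")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Score an odor-profile matrix on the hedonic scale
#'
#' The standard clean-up and scoring sequence: threshold sub-noise
#' applicabilities (dropping descriptors left empty), resolve descriptor
#' aliases against the vocabulary, then apply the tone-weighted-average
#' estimator. All drops and merges are reported, never silent.
#'
#' @param profile An [odor_profile_matrix()] or path to one.
#' @param vocabulary A [hedonic_vocabulary()] or path to one.
#' @param aliases,drop Passed to [apply_descriptor_aliases()].
#' @param threshold Noise threshold for [clean_profile()].
#' @return List: `scores` (data frame), `dropped_columns`, `alias_log`, `n`,
#'   `n_odorless`, `manifest`.
#' @export
run_profile_to_hedonics <- function(profile, vocabulary, aliases = NULL,
                                    drop = character(0), threshold = 4) {
  inputs <- list(profile = profile, vocabulary = vocabulary)
  if (is.character(profile)) profile <- read_profile_matrix(profile)
  if (is.character(vocabulary)) vocabulary <- read_vocabulary(vocabulary)
  if (nrow(profile) == 0L) stop("empty profile matrix", call. = FALSE)
  cleaned <- clean_profile(profile, threshold)
  aliased <- apply_descriptor_aliases(cleaned, aliases, drop,
                                      vocabulary = vocabulary)
  scores <- estimate_hedonic_eq1(aliased, vocabulary)
  list(
    scores = scores,
    dropped_columns = attr(cleaned, "dropped_columns"),
    alias_log = attr(aliased, "alias_log"),
    n = nrow(scores),
    n_odorless = sum(scores$flags == "odorless"),
    manifest = run_manifest("profile_to_hedonics", inputs,
                            config = list(threshold = threshold))
  )
}

#' Relate hedonic scores to molecular features
#'
#' Inner-joins scores and molecules on `id` (mismatches reported, never
#' silently dropped into a changed n), then either evaluates a preset
#' equation or fits the requested term list, and derives the analytic
#' properties: pleasantness threshold (null crossing), hedonic optimum, and
#' the pleasant fraction of the set.
#'
#' @param scores Score data frame (`id`, `hedonic_score`).
#' @param molecules Molecule table (data frame or path); featurized unless it
#'   already carries feature columns (`n_at` etc.).
#' @param terms Term list for fitting (ignored when `preset` given).
#' @param preset Preset id to evaluate instead of fitting.
#' @param exclude Passed to [fit_hedonic_model()].
#' @return List: `model`, `predictions`, `null_crossing`, `optimum`,
#'   `pleasant`, `n`, `n_unmatched`, `manifest`.
#' @export
run_structure_regression <- function(scores, molecules,
                                     terms = c("(Intercept)", "n_at", "i_ox",
                                               "i_sul"),
                                     preset = NULL, exclude = "none") {
  inputs <- list(scores = scores, molecules = molecules)
  if (is.character(molecules)) molecules <- read_molecule_table(molecules)
  features <- if ("n_at" %in% names(molecules)) molecules else
    featurize_table(molecules)
  matched <- intersect(scores$id, features$id)
  if (length(matched) == 0L) {
    stop("empty join: no ids shared between scores and molecules",
         call. = FALSE)
  }
  n_unmatched <- length(union(scores$id, features$id)) - length(matched)
  scores_m <- scores[scores$id %in% matched, , drop = FALSE]
  features_m <- features[features$id %in% matched, , drop = FALSE]
  if (is.null(preset)) {
    model <- fit_hedonic_model(features_m, scores_m, terms, exclude = exclude)
  } else {
    model <- resolve_model(preset)
  }
  predictions <- predict_hedonic(model, features_m)
  cross <- tryCatch(null_crossing(model), error = function(e) NULL)
  list(
    model = model,
    predictions = predictions,
    null_crossing = cross,
    optimum = optimum_nat(model),
    pleasant = classify_pleasant(predictions),
    n = length(matched),
    n_unmatched = n_unmatched,
    manifest = run_manifest("structure_regression", inputs,
                            config = list(terms = terms, preset = preset,
                                          exclude = exclude))
  )
}

#' Search a profile matrix for a hedonic first principal component
#'
#' The full dimension-extraction workflow: normalize skewed variables
#' (per-column overrides win over the skewness rule), autoscale, PCA,
#' cross-validated Q2, and the combined loading-tone / retention decision.
#' The weighted-average hedonic estimates of the same (cleaned, untransformed)
#' matrix are computed alongside for the score-score correlation.
#'
#' @param profile An [odor_profile_matrix()] or path.
#' @param vocabulary A [hedonic_vocabulary()] or path.
#' @param overrides Per-column transform overrides.
#' @param n_components Components for PCA and Q2.
#' @param folds Q2 deletion groups.
#' @param q2_threshold PC1 retention threshold.
#' @param threshold Applicability noise threshold.
#' @param seed Integer seed (Q2 cell assignment).
#' @return List: `pca`, `q2`, `decision`, `eq1_scores`, `transform_log`,
#'   `manifest`.
#' @export
run_hedonic_dimension <- function(profile, vocabulary, overrides = NULL,
                                  n_components = 2L, folds = 7L,
                                  q2_threshold = 0.13, threshold = 4, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  inputs <- list(profile = profile, vocabulary = vocabulary)
  if (is.character(profile)) profile <- read_profile_matrix(profile)
  if (is.character(vocabulary)) vocabulary <- read_vocabulary(vocabulary)
  cleaned <- clean_profile(profile, threshold)
  eq1 <- estimate_hedonic_eq1(cleaned, vocabulary)
  keep <- rowSums(cleaned) > 0
  transformed <- transform_for_normality(cleaned[keep, , drop = FALSE],
                                         overrides)
  scaled <- autoscale(transformed)
  pca <- run_pca(scaled, n_components, tones = vocabulary)
  q2 <- q2_cross_validation(scaled, n_components, folds, seed = seed)
  decision <- hedonic_decision(pca, vocabulary,
                               eq1_scores = eq1[keep, , drop = FALSE],
                               q2 = q2, q2_threshold = q2_threshold)
  list(
    pca = pca,
    q2 = q2,
    decision = decision,
    eq1_scores = eq1,
    transform_log = attr(transformed, "transform_log"),
    manifest = run_manifest("hedonic_dimension", inputs,
                            config = list(n_components = n_components,
                                          folds = folds,
                                          q2_threshold = q2_threshold,
                                          threshold = threshold),
                            seed = seed)
  )
}
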