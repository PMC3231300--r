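# Synthetic odorant sets and profile matrices with planted ground truth, so
# the scoring -> PCA -> regression pipeline can be validated end to end
# without the (undeposited) literature datasets.

#' Configuration for the synthetic-study generator
#'
#' Defaults emulate the composition of the published chemical sets: heavy-atom
#' counts uniform on 2..22, about 73% of molecules containing oxygen, small
#' probabilities for sulfur, carboxylic-acid, amine and chlorine groups, and
#' hedonic truth generated from a published prediction equation plus Gaussian
#' noise. Profile parameters control the planted-hedonic-dimension matrix:
#' descriptor tones drawn uniform on [-4, 4], a Gaussian kernel of width
#' `tau` (tone units) concentrating applicability on descriptors whose tone
#' is close to the odorant's true score, a Bernoulli sparsity mask, and
#' truncated-Gaussian applicability noise.
#'
#' @param n_molecules Number of molecules.
#' @param nat_range Integer range for the heavy-atom-count draw.
#' @param nat_prob Optional probability weights over
#'   `nat_range[1]:nat_range[2]`; uniform when `NULL`. Lets a set emulate a
#'   size distribution concentrated around its mean (e.g. a perfumery
#'   inventory) instead of the flat default.
#' @param p_ox,p_sul,p_acid,p_amine,p_cl Functional-group probabilities;
#'   `p_acid <= p_ox` (an acid without oxygen is impossible).
#' @param p_formula_only Fraction of molecules emitted without SMILES
#'   (formula plus explicit acid/amine flags), exercising the tri-state
#'   featurizer path.
#' @param truth_equation Preset id used as hedonic ground truth.
#' @param noise_sd Gaussian noise sd on true hedonic scores.
#' @param n_descriptors,sparsity,tau,applicability_noise_sd Profile-matrix
#'   parameters: vocabulary size, Bernoulli keep-probability of a
#'   descriptor-odorant cell, kernel width in tone units, and sd of the
#'   additive applicability noise (truncated at zero).
#' @param seed Integer seed; mandatory, every stochastic operation derives
#'   from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 300L, nat_range = c(2L, 22L),
                             nat_prob = NULL,
                             p_ox = 0.73, p_sul = 0.06, p_acid = 0.05,
                             p_amine = 0.04, p_cl = 0.03,
                             p_formula_only = 0.1,
                             truth_equation = "eq11", noise_sd = 0.5,
                             n_descriptors = 40L, sparsity = 0.5,
                             tau = 0.8, applicability_noise_sd = 2,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(p_ox, p_sul, p_acid, p_amine, p_cl, p_formula_only, sparsity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (p_acid > p_ox) {
    stop("impossible configuration: p_acid > p_ox (every carboxylic acid contains oxygen)",
         call. = FALSE)
  }
  if (noise_sd < 0 || applicability_noise_sd < 0 || tau < 0) {
    stop("noise sds and tau must be non-negative", call. = FALSE)
  }
  if (sparsity <= 0) stop("sparsity must be in (0, 1]", call. = FALSE)
  if (!is.null(nat_prob)) {
    if (length(nat_prob) != diff(nat_range) + 1L || any(nat_prob < 0) ||
        sum(nat_prob) <= 0) {
      stop("nat_prob must be non-negative weights over nat_range[1]:nat_range[2]",
           call. = FALSE)
    }
  }
  resolve_model(truth_equation)  # validate the preset id
  structure(list(
    n_molecules = as.integer(n_molecules), nat_range = as.integer(nat_range),
    nat_prob = nat_prob,
    p_ox = p_ox, p_sul = p_sul, p_acid = p_acid, p_amine = p_amine,
    p_cl = p_cl, p_formula_only = p_formula_only,
    truth_equation = truth_equation, noise_sd = noise_sd,
    n_descriptors = as.integer(n_descriptors), sparsity = sparsity,
    tau = tau, applicability_noise_sd = applicability_noise_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Assemble a linear-chain molecule carrying the drawn groups as branches.
# Returns smiles, Hill formula, and the true feature row. Groups are simple
# terminal fragments (carboxyl, hydroxyl, thiol, amino, chloro) on a
# saturated carbon chain, so implicit-hydrogen counts follow from valence.
.build_molecule <- function(n_at, i_ox, i_sul, i_acid, i_amine, i_cl) {
  frags <- character(0)
  if (i_acid) frags <- c(frags, "C(=O)O")
  if (i_ox && !i_acid) frags <- c(frags, "O")
  if (i_sul) frags <- c(frags, "S")
  if (i_amine) frags <- c(frags, "N")
  if (i_cl) frags <- c(frags, "Cl")
  frag_heavy <- sum(c("C(=O)O" = 3, O = 1, S = 1, N = 1, Cl = 1)[frags])
  if (length(frag_heavy) == 0L) frag_heavy <- 0
  n_chain <- n_at - frag_heavy
  n_chain_min <- max(1L, length(frags))
  if (n_chain < n_chain_min) {
    n_chain <- n_chain_min
    n_at <- n_chain + frag_heavy
  }
  smiles <- paste(vapply(seq_len(n_chain), function(i) {
    if (i <= length(frags)) paste0("C(", frags[i], ")") else "C"
  }, character(1)), collapse = "")
  # implicit hydrogens by valence on the saturated skeleton
  h_chain <- sum(vapply(seq_len(n_chain), function(i) {
    4L - (i > 1L) - (i < n_chain) - (i <= length(frags))
  }, integer(1)))
  h_frag <- sum(c("C(=O)O" = 1, O = 1, S = 1, N = 2, Cl = 0)[frags])
  if (length(h_frag) == 0L) h_frag <- 0
  counts <- c(C = n_chain + i_acid, H = h_chain + h_frag, Cl = i_cl,
              N = i_amine, O = 2L * i_acid + as.integer(i_ox && !i_acid),
              S = i_sul)
  counts <- counts[counts > 0]
  formula <- paste0(names(counts),
                    ifelse(counts > 1, counts, ""), collapse = "")
  list(smiles = smiles, formula = formula, n_at = n_at)
}

#' Generate a synthetic molecule set with known features
#'
#' Draws heavy-atom counts and functional-group indicators per the
#' configuration, builds a consistent linear-chain SMILES and Hill formula
#' for each molecule, and returns both the molecule table (as a user would
#' supply it) and the ground-truth feature table. A configured fraction of
#' molecules is emitted formula-only with explicit acid/amine flags.
#' Heavy-atom counts are bumped to the minimum the drawn groups require, so
#' the realized minimum can exceed `nat_range[1]` for group-rich molecules.
#'
#' @param cfg A [generator_config()].
#' @return List: `molecules` (data frame `id`, `smiles`, `formula`,
#'   `is_acid`, `is_amine`), `features` (ground truth: `id`, `n_at`, `i_ox`,
#'   `i_sul`, `i_acid`, `i_amine`, `i_cl`).
#' @export
generate_molecules <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_molecules
  n_at <- sample(cfg$nat_range[1]:cfg$nat_range[2], n, replace = TRUE,
                 prob = cfg$nat_prob)
  i_acid <- stats::rbinom(n, 1, cfg$p_acid)
  # acid forces oxygen; keep the oxygen marginal at p_ox
  p_ox_rest <- if (cfg$p_acid < 1) (cfg$p_ox - cfg$p_acid) / (1 - cfg$p_acid) else 1
  i_ox <- ifelse(i_acid == 1, 1L, stats::rbinom(n, 1, p_ox_rest))
  i_sul <- stats::rbinom(n, 1, cfg$p_sul)
  i_amine <- stats::rbinom(n, 1, cfg$p_amine)
  i_cl <- stats::rbinom(n, 1, cfg$p_cl)
  formula_only <- stats::runif(n) < cfg$p_formula_only
  built <- lapply(seq_len(n), function(i) {
    .build_molecule(n_at[i], i_ox[i], i_sul[i], i_acid[i], i_amine[i], i_cl[i])
  })
  ids <- sprintf("mol%04d", seq_len(n))
  molecules <- data.frame(
    id = ids,
    smiles = ifelse(formula_only, NA_character_,
                    vapply(built, `[[`, character(1), "smiles")),
    formula = vapply(built, `[[`, character(1), "formula"),
    is_acid = ifelse(formula_only, i_acid == 1, NA),
    is_amine = ifelse(formula_only, i_amine == 1, NA),
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    id = ids,
    n_at = vapply(built, `[[`, numeric(1), "n_at"),
    i_ox = i_ox, i_sul = i_sul, i_acid = i_acid, i_amine = i_amine,
    i_cl = i_cl, stringsAsFactors = FALSE
  )
  list(molecules = molecules, features = features)
}

#' Generate true hedonic scores from a preset equation plus noise
#'
#' @param features Feature table (as from [generate_molecules()]).
#' @param equation Preset id; the planted truth model.
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return Data frame `id`, `hedonic_score` (clipped to [-4, 4]), `method`
#'   (`"truth"`), `flags` (`"clipped"` where the noise draw left the scale).
#' @export
generate_hedonic_truth <- function(features, equation = "eq11",
                                   noise_sd = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  pred <- predict_hedonic(equation, features)$hedonic_score
  raw <- pred + stats::rnorm(length(pred), 0, noise_sd)
  clipped <- raw < -4 | raw > 4
  data.frame(id = features$id,
             hedonic_score = pmin(4, pmax(-4, raw)),
             method = "truth",
             flags = ifelse(clipped, "clipped", ""),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic descriptor vocabulary
#'
#' Descriptor tones drawn uniform on [-4, 4]; redrawn (deterministically,
#' from the same stream) until both signs are represented, since a one-sided
#' vocabulary cannot carry a hedonic dimension.
#'
#' @param n_descriptors Vocabulary size.
#' @param seed Integer seed.
#' @return A [hedonic_vocabulary()].
#' @export
generate_vocabulary <- function(n_descriptors = 40L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_descriptors >= 2L)
  set.seed(seed)
  repeat {
    tones <- stats::runif(n_descriptors, -4, 4)
    if (min(tones) < 0 && max(tones) > 0) break
  }
  hedonic_vocabulary(sprintf("syn%03d", seq_len(n_descriptors)), tones,
                     provenance = "synthetic")
}

#' Generate an odor-profile matrix around known hedonic scores
#'
#' For each odorant, descriptor applicability is concentrated on descriptors
#' whose hedonic tone lies close to the odorant's true score: weight
#' proportional to `exp(-(tone - score)^2 / (2 tau^2))`, times a Bernoulli
#' sparsity mask, scaled so the row maximum lands in the upper half of the
#' 0-100 scale, plus truncated-Gaussian noise. The weighted-average hedonic
#' estimator applied to such a matrix recovers the planted scores, and its
#' first principal component aligns with the descriptor tones. With
#' `tau = 0` all weight goes to the nearest-tone descriptor. Odorants with
#' missing scores, or rows fully removed by the sparsity mask, come out
#' all-zero (flagged odorless downstream).
#'
#' @param scores Data frame `id`, `hedonic_score` (the planted truth).
#' @param vocabulary A [hedonic_vocabulary()] whose tones span both signs.
#' @param sparsity,tau,applicability_noise_sd See [generator_config()].
#' @param seed Integer seed.
#' @return An [odor_profile_matrix()] (odorants x descriptors, 0-100).
#' @export
generate_profile_matrix <- function(scores, vocabulary, sparsity = 0.5,
                                    tau = 0.8, applicability_noise_sd = 2,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(vocabulary, "hedonic_vocabulary"))
  tones <- unname(vocabulary)
  if (max(tones) == min(tones)) {
    stop("vocabulary tones are all equal: planted scores would be unrecoverable",
         call. = FALSE)
  }
  if (!(min(tones) < 0 && max(tones) > 0)) {
    stop("vocabulary tones must span both signs", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(scores)
  J <- length(tones)
  m <- matrix(0, n, J, dimnames = list(scores$id, names(vocabulary)))
  for (i in seq_len(n)) {
    s <- scores$hedonic_score[i]
    if (!is.finite(s)) next
    kern <- if (tau == 0) {
      as.numeric(seq_len(J) == which.min(abs(tones - s)))
    } else {
      exp(-(tones - s)^2 / (2 * tau^2))
    }
    w <- kern * stats::rbinom(J, 1, sparsity)
    if (max(w) > 0) {
      w <- w / max(w) * stats::runif(1, 50, 95)
      w <- w + stats::rnorm(J, 0, applicability_noise_sd) * (w > 0)
      w <- pmin(100, pmax(0, w))
    }
    m[i, ] <- w
  }
  odor_profile_matrix(m)
}

#' Simulate a complete synthetic study
#'
#' Molecules, planted hedonic truth, a synthetic vocabulary, and a profile
#' matrix whose weighted-average scores track the truth - everything needed
#' to exercise scoring, PCA and regression with a known answer. Sub-seeds
#' for the four stochastic stages are derived from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List: `molecules`, `features`, `truth`, `vocabulary`, `profile`,
#'   `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  mols <- generate_molecules(cfg)
  truth <- generate_hedonic_truth(mols$features, cfg$truth_equation,
                                  cfg$noise_sd, seed = cfg$seed + 1L)
  vocab <- generate_vocabulary(cfg$n_descriptors, seed = cfg$seed + 2L)
  profile <- generate_profile_matrix(truth, vocab, sparsity = cfg$sparsity,
                                     tau = cfg$tau,
                                     applicability_noise_sd = cfg$applicability_noise_sd,
                                     seed = cfg$seed + 3L)
  list(molecules = mols$molecules, features = mols$features, truth = truth,
       vocabulary = vocab, profile = profile, config = cfg)
}

#' Write a simulated study to delimited text files
#'
#' Emits the molecule table, ground-truth score table, vocabulary, and
#' profile matrix under `dir`.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @param sep Field separator.
#' @return Invisibly, the vector of paths written.
#' @export
write_study <- function(study, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("molecules.csv", "truth.csv", "vocabulary.csv",
                            "profile.csv"))
  utils::write.table(study$molecules, paths[1], sep = sep, row.names = FALSE,
                     quote = TRUE)
  utils::write.table(study$truth, paths[2], sep = sep, row.names = FALSE,
                     quote = TRUE)
  utils::write.table(
    data.frame(descriptor = names(study$vocabulary),
               hedonic_tone = unname(study$vocabulary)),
    paths[3], sep = sep, row.names = FALSE, quote = TRUE)
  utils::write.table(
    data.frame(id = rownames(study$profile),
               as.data.frame(unclass(study$profile)), check.names = FALSE),
    paths[4], sep = sep, row.names = FALSE, quote = TRUE)
  invisible(paths)
}
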