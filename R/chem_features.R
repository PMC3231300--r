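# Molecular featurization: heavy-atom counts and functional-group indicators
# from SMILES and/or molecular formulas.

# Monoisotopic-average atomic masses for the elements that occur in volatile
# odorants (and a few more so exotic formulas fail loudly rather than wrongly).
.atomic_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Se = 78.971, Te = 127.60, As = 74.922, Bi = 208.980, Na = 22.990,
  K = 39.098, Sn = 118.710
)

#' Parse a molecular formula into per-element atom counts
#'
#' Accepts Hill-style formulas such as `"C7H6O"` or `"H2S"`: element symbols
#' (one upper-case letter optionally followed by one lower-case letter) each
#' followed by an optional integer multiplier. Nested groups and charges are
#' not supported; odorant formulas do not need them.
#'
#' @param formula Molecular formula string.
#' @return Named integer vector of per-element counts.
#' @examples
#' parse_formula("C7H6O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(parts, collapse = "") != formula) {
    bad <- sub("^([A-Za-z0-9]*).*", "\\1",
               substr(formula, nchar(paste(parts, collapse = "")) + 1L,
                      nchar(formula)))
    stop(sprintf("malformed formula '%s': unexpected token near '%s'",
                 formula, if (nzchar(bad)) bad else formula), call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", parts)
  mult <- sub("^[A-Z][a-z]?", "", parts)
  counts <- ifelse(nzchar(mult), suppressWarnings(as.integer(mult)), 1L)
  unknown <- setdiff(elements, names(.atomic_masses))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s) in formula '%s': %s",
                 formula, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(counts < 1L | is.na(counts))) {
    stop(sprintf("invalid multiplier in formula '%s'", formula), call. = FALSE)
  }
  out <- tapply(counts, elements, sum)
  storage.mode(out) <- "integer"
  # drop tapply's dimnames apparatus, keep a plain named vector
  structure(as.integer(out), names = names(out))
}

# Parse a SMILES string into element symbols and a bond table (a1, a2, order),
# delegating structure perception (including kekulization of aromatic SMILES)
# to Open Babel via ChemmineR. Hydrogens are implicit; `formula` is the
# hydrogen-complete Hill formula.
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("smiles must be a single non-empty string", call. = FALSE)
  }
  # bond-free molecules (one heavy atom: methane "C", hydrogen sulfide "S",
  # ammonia "N") cannot round-trip through an SDF; handle them directly with
  # standard neutral valences
  single <- regmatches(smiles, regexec("^\\[?([A-Z][a-z]?)H?[0-9]*\\]?$",
                                       smiles))[[1]]
  if (length(single) == 2L) {
    el <- single[2]
    if (!el %in% names(.atomic_masses)) {
      stop(sprintf("could not parse SMILES '%s': unknown element '%s'",
                   smiles, el), call. = FALSE)
    }
    valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L, Cl = 1L,
                 Br = 1L, I = 1L)
    nh <- if (el %in% names(valence)) valence[[el]] else 0L
    return(list(
      elements = el,
      bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)),
      formula = paste0(el, if (nh > 0L) paste0("H", if (nh > 1L) nh else ""))
    ))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop(sprintf("could not parse SMILES '%s': %s", smiles,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) == 0L) {
    stop(sprintf("could not parse SMILES '%s': no atoms perceived", smiles),
         call. = FALSE)
  }
  elements <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf[[1]])
  # single-atom molecules get a placeholder zero row with no order column
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    d <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    d[d$a1 > 0L & d$a2 > 0L, , drop = FALSE]
  }
  mf <- as.character(ChemmineR::MF(sdf, addH = TRUE))
  list(elements = elements, bonds = bonds, formula = mf)
}

# Indices of atoms bonded to atom i, with the bond orders.
.neighbours <- function(parsed, i) {
  b <- parsed$bonds
  hit <- b$a1 == i | b$a2 == i
  data.frame(atom = ifelse(b$a1[hit] == i, b$a2[hit], b$a1[hit]),
             order = b$order[hit])
}

# Is atom i a carbonyl carbon (C with a double bond to O)?
.is_carbonyl_carbon <- function(parsed, i) {
  if (parsed$elements[i] != "C") return(FALSE)
  nb <- .neighbours(parsed, i)
  any(parsed$elements[nb$atom] == "O" & nb$order == 2L)
}

#' Detect a carboxylic-acid group in a SMILES string
#'
#' A carboxyl is a carbon carrying both a double-bonded oxygen and a
#' single-bonded hydroxyl oxygen (an oxygen with no other heavy neighbour, so
#' esters and anhydrides do not match). Carboxylate anions are out of scope:
#' odorants are neutral volatiles.
#'
#' @param smiles SMILES string.
#' @return `TRUE` if the molecule contains a carboxyl group.
#' @examples
#' detect_acid("CC(=O)O")   # acetic acid: TRUE
#' detect_acid("CC(=O)OC")  # methyl acetate: FALSE
#' @export
detect_acid <- function(smiles) {
  p <- parse_smiles(smiles)
  carbons <- which(p$elements == "C")
  for (i in carbons) {
    nb <- .neighbours(p, i)
    ox <- nb[p$elements[nb$atom] == "O", , drop = FALSE]
    if (!any(ox$order == 2L)) next
    hydroxyls <- ox$atom[ox$order == 1L]
    for (o in hydroxyls) {
      # hydroxyl: the singly bonded O has no heavy neighbour besides this C
      if (nrow(.neighbours(p, o)) == 1L) return(TRUE)
    }
  }
  FALSE
}

#' Detect an amine group in a SMILES string
#'
#' An amine nitrogen has only single bonds, only carbon (or implicit
#' hydrogen) neighbours, and no neighbouring carbonyl carbon. This excludes
#' amides, nitro groups, nitriles, azides and aza-aromatics, while keeping
#' primary through tertiary aliphatic amines and aryl amines such as aniline
#' (the fishy-urinous odor family).
#'
#' @param smiles SMILES string.
#' @return `TRUE` if the molecule contains an amine nitrogen.
#' @examples
#' detect_amine("CCN")      # ethylamine: TRUE
#' detect_amine("CC(=O)N")  # acetamide: FALSE
#' @export
detect_amine <- function(smiles) {
  p <- parse_smiles(smiles)
  nitrogens <- which(p$elements == "N")
  for (i in nitrogens) {
    nb <- .neighbours(p, i)
    if (nrow(nb) > 0L && any(nb$order != 1L)) next        # nitro/nitrile/imine
    if (nrow(nb) > 0L && any(p$elements[nb$atom] != "C")) next  # N-N, N-O ...
    carbonyl <- vapply(nb$atom, function(j) .is_carbonyl_carbon(p, j),
                       logical(1))
    if (nrow(nb) > 0L && any(carbonyl)) next              # amide
    return(TRUE)
  }
  FALSE
}

#' Construct a molecule record
#'
#' At least one of `smiles` and `formula` must be given. Explicit acid/amine
#' flags, when supplied, override structure-derived detection downstream.
#'
#' @param id Identifier string.
#' @param smiles Optional SMILES string.
#' @param formula Optional molecular formula (Hill style).
#' @param is_acid,is_amine Optional logical flags overriding detection.
#' @return A list of class `molecule_record`.
#' @export
molecule_record <- function(id, smiles = NULL, formula = NULL,
                            is_acid = NA, is_amine = NA) {
  if (is.null(smiles) || (length(smiles) == 1L && (is.na(smiles) || !nzchar(smiles)))) smiles <- NULL
  if (is.null(formula) || (length(formula) == 1L && (is.na(formula) || !nzchar(formula)))) formula <- NULL
  if (is.null(smiles) && is.null(formula)) {
    stop(sprintf("molecule '%s': need at least one of smiles or formula", id),
         call. = FALSE)
  }
  structure(list(id = as.character(id), smiles = smiles, formula = formula,
                 is_acid = as.logical(is_acid), is_amine = as.logical(is_amine)),
            class = "molecule_record")
}

#' Compute molecular features for regression on hedonic scores
#'
#' Produces the heavy-atom count `n_at` (all atoms except hydrogen), the
#' presence indicators for oxygen, sulfur and chlorine, the structural
#' carboxylic-acid and amine indicators, per-element atom counts, and the
#' molecular weight. When the record carries both a SMILES and a formula,
#' their heavy-atom counts must agree. Acid/amine indicators come from
#' explicit flags when present, from SMILES substructure detection otherwise;
#' a formula-only record without flags yields `NA` ("undetermined") for both,
#' which model fitting refuses to consume silently.
#'
#' @param mol A [molecule_record()].
#' @return A list of class `molecular_features` with fields `id`, `n_at`,
#'   `i_ox`, `i_sul`, `i_cl`, `i_acid`, `i_amine`, `atom_counts`,
#'   `molecular_weight`.
#' @examples
#' featurize(molecule_record("benzaldehyde", smiles = "O=Cc1ccccc1"))
#' @export
featurize <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  parsed <- NULL
  if (!is.null(mol$smiles)) {
    parsed <- parse_smiles(mol$smiles)
    counts <- parse_formula(parsed$formula)
  } else {
    counts <- parse_formula(mol$formula)
  }
  if (!is.null(mol$smiles) && !is.null(mol$formula)) {
    counts_f <- parse_formula(mol$formula)
    nat_f <- sum(counts_f[names(counts_f) != "H"])
    nat_s <- sum(counts[names(counts) != "H"])
    if (nat_f != nat_s) {
      stop(sprintf(
        "molecule '%s': heavy-atom count from SMILES (%d) and formula (%d) disagree",
        mol$id, nat_s, nat_f), call. = FALSE)
    }
  }
  heavy <- counts[names(counts) != "H"]
  n_at <- as.integer(sum(heavy))
  cnt <- function(el) if (el %in% names(counts)) counts[[el]] else 0L

  i_acid <- mol$is_acid
  i_amine <- mol$is_amine
  if (is.na(i_acid)) i_acid <- if (!is.null(parsed)) detect_acid(mol$smiles) else NA
  if (is.na(i_amine)) i_amine <- if (!is.null(parsed)) detect_amine(mol$smiles) else NA
  if (isTRUE(i_acid) && cnt("O") < 1L) {
    stop(sprintf("molecule '%s': flagged as carboxylic acid but contains no oxygen",
                 mol$id), call. = FALSE)
  }
  if (isTRUE(i_amine) && cnt("N") < 1L) {
    stop(sprintf("molecule '%s': flagged as amine but contains no nitrogen",
                 mol$id), call. = FALSE)
  }
  mw <- sum(.atomic_masses[names(counts)] * counts)
  structure(list(
    id = mol$id,
    n_at = n_at,
    i_ox = as.integer(cnt("O") >= 1L),
    i_sul = as.integer(cnt("S") >= 1L),
    i_cl = as.integer(cnt("Cl") >= 1L),
    i_acid = if (is.na(i_acid)) NA_integer_ else as.integer(i_acid),
    i_amine = if (is.na(i_amine)) NA_integer_ else as.integer(i_amine),
    atom_counts = counts,
    molecular_weight = unname(mw)
  ), class = "molecular_features")
}

#' Featurize a molecule table
#'
#' @param mols Data frame with columns `id` and at least one of `smiles`,
#'   `formula`; optional logical/`"true"`/`"false"` columns `is_acid`,
#'   `is_amine`.
#' @return Data frame with one row per molecule: `id`, `n_at`, `i_ox`,
#'   `i_sul`, `i_cl`, `i_acid`, `i_amine` (integer, `NA` = undetermined),
#'   `n_ox`, `n_nitro`, `molecular_weight`.
#' @export
featurize_table <- function(mols) {
  stopifnot(is.data.frame(mols), "id" %in% names(mols))
  as_flag <- function(x) {
    if (is.null(x)) return(rep(NA, nrow(mols)))
    if (is.logical(x)) return(x)
    x <- tolower(trimws(as.character(x)))
    ifelse(x %in% c("true", "t", "1", "yes"), TRUE,
           ifelse(x %in% c("false", "f", "0", "no"), FALSE, NA))
  }
  acid <- as_flag(mols$is_acid)
  amine <- as_flag(mols$is_amine)
  rows <- lapply(seq_len(nrow(mols)), function(i) {
    f <- featurize(molecule_record(
      mols$id[i],
      smiles = if ("smiles" %in% names(mols)) mols$smiles[i] else NULL,
      formula = if ("formula" %in% names(mols)) mols$formula[i] else NULL,
      is_acid = acid[i], is_amine = amine[i]))
    data.frame(id = f$id, n_at = f$n_at, i_ox = f$i_ox, i_sul = f$i_sul,
               i_cl = f$i_cl, i_acid = f$i_acid, i_amine = f$i_amine,
               n_ox = if ("O" %in% names(f$atom_counts)) f$atom_counts[["O"]] else 0L,
               n_nitro = if ("N" %in% names(f$atom_counts)) f$atom_counts[["N"]] else 0L,
               molecular_weight = f$molecular_weight,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a chemical set by its basic composition
#'
#' One row per set: number of compounds, min/max/mean heavy-atom count, and
#' the number of molecules containing oxygen, nitrogen, sulfur or chlorine,
#' and the number of carboxylic acids and amines (undetermined indicators
#' counted as absent, with a warning).
#'
#' @param features Data frame as returned by [featurize_table()].
#' @return One-row data frame.
#' @export
summarize_set <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) stop("empty molecule set", call. = FALSE)
  und <- sum(is.na(features$i_acid)) + sum(is.na(features$i_amine))
  if (und > 0L) {
    warning(sprintf("%d undetermined acid/amine indicator(s) counted as absent",
                    und), call. = FALSE)
  }
  data.frame(
    n = nrow(features),
    nat_min = min(features$n_at),
    nat_max = max(features$n_at),
    nat_mean = mean(features$n_at),
    n_oxygen = sum(features$i_ox),
    n_nitrogen = sum(features$n_nitro >= 1L),
    n_sulfur = sum(features$i_sul),
    n_chlorine = sum(features$i_cl),
    n_acid = sum(features$i_acid, na.rm = TRUE),
    n_amine = sum(features$i_amine, na.rm = TRUE)
  )
}

#' Read a delimited molecule table
#'
#' Expected columns: `id`, then `smiles` and/or `formula`, optional `is_acid`
#' and `is_amine`.
#'
#' @param path File path.
#' @param sep Field separator (comma by default, tab accepted).
#' @return Data frame.
#' @export
read_molecule_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"id" %in% names(df)) stop("molecule table needs an 'id' column", call. = FALSE)
  df
}
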