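#' Sliding-window aggregation-propensity profile
#'
#' Maps each residue to the arithmetic mean of per-residue propensity values
#' (a3v) over a window centered on it, yielding one window-averaged value
#' (a4v) per position. Windows are truncated (shrink one-sided) at the
#' sequence ends so that every residue, including terminal ones, carries a
#' value and the length-normalized summary is defined for short domains.
#'
#' @param sequence A residue string over the 20-letter alphabet.
#' @param scale Named numeric a3v scale (see [sg_propensity_scale()]).
#' @param window Odd positive window size; must not exceed the sequence
#'   length.
#' @return Numeric vector of a4v values, one per residue.
#' @export
sg_window_profile <- function(sequence, scale, window) {
  scale <- validate_scale(scale)
  if (!is.numeric(window) || length(window) != 1L || window < 1L ||
      window %% 2 == 0) {
    abort("`window` must be an odd positive integer.",
          class = "sgpred_parameter_error")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  check_residues(res)
  n <- length(res)
  if (n < window) {
    abort(sprintf("Sequence length %d is shorter than window %d.", n, window),
          class = "sgpred_length_error")
  }
  a3v <- unname(scale[res])
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, a3v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

check_residues <- function(res) {
  bad <- which(!(res %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    abort(sprintf("Invalid residue '%s' at position %d.", res[bad[1]], bad[1]),
          class = "sgpred_invalid_residue")
  }
  invisible(res)
}

#' Length-normalized aggregation score (Na4vSS)
#'
#' Summarizes the window-averaged profile of [sg_window_profile()] into a
#' single per-sequence score: the mean a4v over all positions, times 100.
#' The score carries both positive (aggregation-prone) and negative
#' (aggregation-resistant) values.
#'
#' @inheritParams sg_window_profile
#' @return A single numeric Na4vSS score.
#' @export
sg_na4vss <- function(sequence, scale, window) {
  mean(sg_window_profile(sequence, scale, window)) * 100
}

#' Min-max normalization of Na4vSS scores
#'
#' The classifier consumes only non-negative aggregation inputs, so raw
#' scores are rescaled to \[0, 1\] between the least (`na4vss_min`) and most
#' (`na4vss_max`) aggregation-prone reference sequences; out-of-range scores
#' are clamped to the nearest bound.
#'
#' @param raw Numeric vector of raw Na4vSS scores.
#' @param bounds An [sg_norm_bounds()] object.
#' @return Numeric vector in \[0, 1\].
#' @export
sg_normalize_na4vss <- function(raw, bounds) {
  bounds <- validate_bounds(bounds)
  pmin(pmax((raw - bounds$na4vss_min) /
              (bounds$na4vss_max - bounds$na4vss_min), 0), 1)
}

#' Fractional charge of one residue at a given pH
#'
#' Henderson-Hasselbalch fractional ionization: a basic group carries
#' `+1 / (1 + 10^(pH - pKa))`, an acidic group `-1 / (1 + 10^(pKa - pH))`,
#' and non-ionizable residues are neutral. At `pH == pKa` the magnitude is
#' exactly 0.5.
#'
#' @param residue One-letter residue code(s); vectorized.
#' @param pH The pH at which charge is evaluated.
#' @param pka A pKa table from [sg_pka_table()].
#' @return Numeric charge(s) in \[-1, 1\].
#' @export
sg_residue_charge <- function(residue, pH = 7.0, pka = sg_pka_table()) {
  pka <- validate_pka(pka)
  residue <- toupper(residue)
  check_residues(residue)
  vapply(residue, function(r) {
    if (!r %in% names(pka$pka)) return(0)
    k <- pka$pka[[r]]
    if (pka$polarity[[r]] == "basic") 1 / (1 + 10^(pH - k))
    else -1 / (1 + 10^(k - pH))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Net charge per residue (NCPR)
#'
#' Sums Henderson-Hasselbalch fractional charges over all residues (plus the
#' free terminal groups when `include_termini` is `TRUE`) and divides by the
#' sequence length. NCPR depends only on composition, not residue order.
#'
#' @inheritParams sg_window_profile
#' @inheritParams sg_residue_charge
#' @param include_termini Add the N-terminal amine and C-terminal carboxylate
#'   charges? Off by default, as PrLDs are internal domains.
#' @return A single numeric NCPR in (-1, 1).
#' @export
sg_ncpr <- function(sequence, pH = 7.0, pka = sg_pka_table(),
                    include_termini = FALSE) {
  pka <- validate_pka(pka)
  res <- strsplit(toupper(sequence), "")[[1]]
  check_residues(res)
  total <- sum(sg_residue_charge(res, pH = pH, pka = pka))
  if (isTRUE(include_termini)) {
    total <- total +
      1 / (1 + 10^(pH - pka$nterm_pka)) -
      1 / (1 + 10^(pka$cterm_pka - pH))
  }
  total / length(res)
}

#' Cysteine percentage
#'
#' The fraction of cysteines in the sequence, as a percentage, used as a
#' proxy for disulfide-bonding potential under oxidative (heat) stress.
#'
#' @inheritParams sg_window_profile
#' @return A single numeric value in \[0, 100\].
#' @export
sg_cys_pct <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  check_residues(res)
  100 * sum(res == "C") / length(res)
}

#' Compute the classifier's three input features per sequence
#'
#' Appends to each record its raw and normalized aggregation score, NCPR and
#' cysteine percentage. Deterministic: identical input and configuration
#' give identical output.
#'
#' @param data A tibble with columns `id` and `sequence` (e.g. from
#'   [sg_parse_fasta()]).
#' @param config An [sg_feature_config()]. When its `bounds` are unset the
#'   `agg_norm` column is `NA` (bounds are normally derived from training
#'   data and stored inside a fitted model).
#' @return `data` with columns `agg_raw`, `agg_norm`, `ncpr`, `cys_pct`
#'   appended.
#' @export
sg_featurize <- function(data, config = sg_feature_config()) {
  stopifnot(is.data.frame(data), all(c("id", "sequence") %in% names(data)))
  if (!inherits(config, "sg_feature_config")) {
    abort("`config` must be an sg_feature_config object.",
          class = "sgpred_parameter_error")
  }
  min_window <- min(config$window_bands[, 2])
  too_short <- nchar(data$sequence) < min_window
  if (any(too_short)) {
    abort(sprintf(
      "Record(s) shorter than the minimum scoring window (%d): %s",
      min_window, paste(data$id[too_short], collapse = ", ")),
      class = "sgpred_length_error")
  }
  agg_raw <- vapply(data$sequence, function(s) {
    sg_na4vss(s, config$scale, window_for_length(nchar(s), config$window_bands))
  }, numeric(1), USE.NAMES = FALSE)
  agg_norm <- if (is.null(config$bounds)) rep(NA_real_, length(agg_raw)) else
    sg_normalize_na4vss(agg_raw, config$bounds)
  dplyr::mutate(
    as_tibble(data),
    agg_raw = agg_raw,
    agg_norm = agg_norm,
    ncpr = vapply(.data$sequence, sg_ncpr, numeric(1), pH = config$pH,
                  pka = config$pka, include_termini = config$include_termini,
                  USE.NAMES = FALSE),
    cys_pct = vapply(.data$sequence, sg_cys_pct, numeric(1), USE.NAMES = FALSE)
  )
}

feature_matrix <- function(features) {
  stopifnot(all(c("agg_norm", "ncpr", "cys_pct") %in% names(features)))
  m <- as.matrix(features[, c("agg_norm", "ncpr", "cys_pct")])
  if (anyNA(m) || any(!is.finite(m))) {
    abort("Feature matrix contains missing or non-finite values; was `agg_norm` computed with bounds?",
          class = "sgpred_input_error")
  }
  m
}
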