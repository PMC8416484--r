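#' Default per-residue aggregation-propensity scale
#'
#' Returns the intrinsic per-residue aggregation-propensity values (a3v) used
#' by the sliding-window scorer. The default values ship as an editable
#' key-value data file (`inst/extdata/aggrescan_a3v.tsv`); every scoring
#' function also accepts an arbitrary scale, so analyses are never tied to
#' this file.
#'
#' @param path Optional path to an alternative scale file (two tab-separated
#'   columns: residue, value; `#` comments allowed).
#' @return A named numeric vector of length 20, one value per canonical
#'   residue.
#' @export
sg_propensity_scale <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aggrescan_a3v.tsv",
                                package = "sgpred", mustWork = TRUE)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "value"),
                           stringsAsFactors = FALSE)
  scale <- setNames(as.numeric(tab$value), toupper(trimws(tab$residue)))
  validate_scale(scale)
}

validate_scale <- function(scale) {
  if (!is.numeric(scale) || is.null(names(scale)) ||
      !setequal(names(scale), AA_ALPHABET) || length(scale) != 20L ||
      anyNA(scale)) {
    abort("A propensity scale must map each of the 20 canonical residues to one finite value.",
          class = "sgpred_parameter_error")
  }
  scale[AA_ALPHABET]
}

#' Default pKa table for side-chain ionization
#'
#' A conventional biochemistry pKa set covering the seven ionizable residues
#' (acidic: D, E, C, Y; basic: H, K, R) plus the free amino and carboxy
#' termini. PrLDs are internal domains of larger proteins, so terminal
#' charges are excluded from NCPR by default (see [sg_feature_config()]).
#'
#' @param path Optional path to an alternative table (three tab-separated
#'   columns: group, pKa, polarity with polarity `acidic` or `basic`; groups
#'   `NTERM`/`CTERM` set the terminal pKas).
#' @return A list with elements `pka` (named numeric), `polarity` (named
#'   character), `nterm_pka`, `cterm_pka`.
#' @export
sg_pka_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pka_default.tsv",
                                package = "sgpred", mustWork = TRUE)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           col.names = c("group", "pka", "polarity"),
                           stringsAsFactors = FALSE)
  tab$group <- toupper(trimws(tab$group))
  term <- tab$group %in% c("NTERM", "CTERM")
  res <- tab[!term, , drop = FALSE]
  out <- list(
    pka = setNames(as.numeric(res$pka), res$group),
    polarity = setNames(tolower(trimws(res$polarity)), res$group),
    nterm_pka = as.numeric(tab$pka[tab$group == "NTERM"][1]),
    cterm_pka = as.numeric(tab$pka[tab$group == "CTERM"][1])
  )
  validate_pka(out)
}

validate_pka <- function(table) {
  need <- c("D", "E", "C", "Y", "H", "K", "R")
  if (!all(need %in% names(table$pka))) {
    abort("pKa table must cover at least D, E, C, Y, H, K, R.",
          class = "sgpred_parameter_error")
  }
  if (!all(table$polarity %in% c("acidic", "basic"))) {
    abort("pKa polarities must be 'acidic' or 'basic'.",
          class = "sgpred_parameter_error")
  }
  vals <- c(table$pka, table$nterm_pka, table$cterm_pka)
  vals <- vals[is.finite(vals)]
  if (any(vals <= 0 | vals >= 14)) {
    abort("All pKa values must lie in (0, 14).", class = "sgpred_parameter_error")
  }
  table
}

#' Feature-extraction configuration
#'
#' Bundles everything [sg_featurize()] needs: the propensity scale, the
#' length-dependent window rule, the pH and pKa table for the net charge per
#' residue, and (optionally) the normalization bounds for the aggregation
#' score.
#'
#' @param scale Named numeric a3v scale (default [sg_propensity_scale()]).
#' @param window_bands Two-column matrix-like of `(max_length, window)`
#'   bands; a sequence uses the window of the first band whose `max_length`
#'   is >= its length. The default follows the classical length-dependent
#'   rule of sliding-window aggregation scoring: window 5 up to 75 residues,
#'   7 up to 175, 9 up to 275, 11 beyond.
#' @param pH pH at which per-residue charges are evaluated; default 7.0
#'   (cytosolic-like).
#' @param pka pKa table from [sg_pka_table()].
#' @param include_termini Include free N-/C-terminal charges in NCPR?
#'   Default `FALSE`: PrLDs are internal domains, so free termini would be
#'   artifactual.
#' @param bounds Optional [sg_norm_bounds()] used to map raw Na4vSS scores
#'   onto \[0, 1\]; when `NULL`, normalized scores are not computed (a model
#'   fit derives bounds from its training data).
#' @return An object of class `sg_feature_config`.
#' @export
sg_feature_config <- function(scale = sg_propensity_scale(),
                              window_bands = default_window_bands(),
                              pH = 7.0,
                              pka = sg_pka_table(),
                              include_termini = FALSE,
                              bounds = NULL) {
  scale <- validate_scale(scale)
  pka <- validate_pka(pka)
  window_bands <- as.matrix(window_bands)
  if (ncol(window_bands) != 2L || any(window_bands[, 2] %% 2 == 0) ||
      any(window_bands[, 2] < 1)) {
    abort("`window_bands` must be (max_length, odd window) rows.",
          class = "sgpred_parameter_error")
  }
  window_bands <- window_bands[order(window_bands[, 1]), , drop = FALSE]
  if (!is.null(bounds)) bounds <- validate_bounds(bounds)
  structure(
    list(scale = scale, window_bands = window_bands, pH = pH, pka = pka,
         include_termini = isTRUE(include_termini), bounds = bounds),
    class = "sg_feature_config"
  )
}

default_window_bands <- function() {
  cbind(max_length = c(75, 175, 275, Inf), window = c(5, 7, 9, 11))
}

#' @export
print.sg_feature_config <- function(x, ...) {
  cat("<sg_feature_config>\n")
  cat("  pH:", x$pH, "| termini:",
      if (x$include_termini) "included" else "excluded", "\n")
  cat("  window bands:",
      paste(sprintf("<=%s:%d", x$window_bands[, 1], x$window_bands[, 2]),
            collapse = " "), "\n")
  if (!is.null(x$bounds)) {
    cat(sprintf("  Na4vSS bounds: [%.3f, %.3f]\n",
                x$bounds$na4vss_min, x$bounds$na4vss_max))
  } else cat("  Na4vSS bounds: unset (derived at fit time)\n")
  invisible(x)
}

#' Normalization bounds for the aggregation score
#'
#' The raw Na4vSS score spans positive and negative values; the classifier
#' consumes it min-max normalized between the scores of the least and most
#' aggregation-prone reference sequences (by default, of the training set).
#'
#' @param na4vss_min,na4vss_max Raw Na4vSS of the least / most
#'   aggregation-prone reference sequence (`na4vss_min < na4vss_max`).
#' @return An object of class `sg_norm_bounds`.
#' @export
sg_norm_bounds <- function(na4vss_min, na4vss_max) {
  validate_bounds(list(na4vss_min = na4vss_min, na4vss_max = na4vss_max))
}

validate_bounds <- function(bounds) {
  lo <- bounds$na4vss_min
  hi <- bounds$na4vss_max
  if (!is.numeric(lo) || !is.numeric(hi) || !is.finite(lo) || !is.finite(hi) ||
      lo >= hi) {
    abort("Normalization bounds require finite na4vss_min < na4vss_max.",
          class = "sgpred_configuration_error")
  }
  structure(list(na4vss_min = as.numeric(lo), na4vss_max = as.numeric(hi)),
            class = "sg_norm_bounds")
}

window_for_length <- function(len, window_bands) {
  idx <- which(window_bands[, 1] >= len)[1]
  if (is.na(idx)) idx <- nrow(window_bands)
  as.integer(window_bands[idx, 2])
}
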