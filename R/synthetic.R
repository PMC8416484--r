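#' Default residue-composition profiles for synthetic PrLDs
#'
#' Two compositional classes emulating the separation observed between
#' heat-recruited and non-recruited prion-like domains. The positive
#' (recruited) profile is enriched in hydrophobic residues (W, F, I, L, V),
#' ionizable residues (H, E, K, R) with cationic mass exceeding anionic so
#' the expected net charge per residue is positive, and carries about 1.5%
#' cysteine. The negative profile is Q/N-rich with G/S/Y padding, slightly
#' anionic (D+E mass above K+R+H) and nearly cysteine-free. Under these
#' profiles the expected class means are ordered positive > negative for
#' aggregation propensity, NCPR and cysteine percentage.
#'
#' @return A list with elements `positive` and `negative`, each a named
#'   numeric vector of 20 residue frequencies summing to 1.
#' @export
sg_default_profiles <- function() {
  positive <- c(
    A = 0.060, C = 0.015, D = 0.030, E = 0.050, F = 0.050,
    G = 0.070, H = 0.030, I = 0.070, K = 0.070, L = 0.080,
    M = 0.015, N = 0.060, P = 0.040, Q = 0.060, R = 0.050,
    S = 0.080, T = 0.050, V = 0.070, W = 0.030, Y = 0.020
  )
  negative <- c(
    A = 0.070, C = 0.001, D = 0.035, E = 0.035, F = 0.010,
    G = 0.120, H = 0.015, I = 0.015, K = 0.025, L = 0.020,
    M = 0.010, N = 0.150, P = 0.060, Q = 0.169, R = 0.020,
    S = 0.120, T = 0.060, V = 0.020, W = 0.004, Y = 0.041
  )
  list(positive = validate_profile(positive),
       negative = validate_profile(negative))
}

validate_profile <- function(freqs) {
  if (!is.numeric(freqs) || !setequal(names(freqs), AA_ALPHABET) ||
      any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    abort("A composition profile needs 20 non-negative residue frequencies summing to 1.",
          class = "sgpred_parameter_error")
  }
  freqs[AA_ALPHABET]
}

#' Expected feature values under a composition profile
#'
#' Closed-form expectations for composition-determined features: the
#' profile-weighted mean per-residue propensity (times 100, the expected
#' Na4vSS of long sequences), the profile-weighted Henderson-Hasselbalch
#' charge (expected NCPR) and the expected cysteine percentage.
#'
#' @param freqs A named residue-frequency vector (see
#'   [sg_default_profiles()]).
#' @param config An [sg_feature_config()] supplying the scale, pH and pKa
#'   table.
#' @return A one-row tibble with columns `e_agg`, `e_ncpr`, `e_cys_pct`.
#' @export
sg_profile_expectation <- function(freqs, config = sg_feature_config()) {
  freqs <- validate_profile(freqs)
  charges <- sg_residue_charge(AA_ALPHABET, pH = config$pH, pka = config$pka)
  tibble(
    e_agg = 100 * sum(freqs * config$scale[AA_ALPHABET]),
    e_ncpr = sum(freqs * charges),
    e_cys_pct = 100 * freqs[["C"]]
  )
}

#' Generate a labeled synthetic PrLD dataset
#'
#' Draws sequences residue by residue (i.i.d.) from class-specific
#' composition profiles — every feature the classifier consumes is
#' composition- or window-average-determined, so no positional structure is
#' imposed — with lengths uniform on `[length_min, length_max]`. Record ids
#' encode class and index (`pos_001`, `neg_001`, ...). Fully deterministic
#' given the seed.
#'
#' @param n_pos,n_neg Number of positive / negative records.
#' @param length_min,length_max Sequence-length range (residues); the
#'   default 60-250 spans typical prion-like domains.
#' @param profiles A list with `positive` and `negative` frequency vectors
#'   (default [sg_default_profiles()]).
#' @param seed Integer seed.
#' @return A labeled tibble with columns `id`, `description`, `sequence`,
#'   `label`.
#' @examples
#' sg_simulate(n_pos = 2, n_neg = 2, seed = 42)
#' @export
sg_simulate <- function(n_pos = 32L, n_neg = 32L, length_min = 60L,
                        length_max = 250L, profiles = sg_default_profiles(),
                        seed = 1L) {
  if (n_pos < 0 || n_neg < 0 || length_min < 1 || length_min > length_max) {
    abort("Invalid generator configuration.", class = "sgpred_parameter_error")
  }
  profiles <- list(positive = validate_profile(profiles$positive),
                   negative = validate_profile(profiles$negative))
  withr::with_seed(as.integer(seed), {
    draw_class <- function(cls, n, tag) {
      if (n == 0L) return(tibble(id = character(0), description = character(0),
                                 sequence = character(0), label = character(0)))
      freqs <- profiles[[cls]]
      lens <- sample.int(length_max - length_min + 1L, n, replace = TRUE) +
        length_min - 1L
      seqs <- vapply(lens, function(len) {
        paste(sample(AA_ALPHABET, len, replace = TRUE, prob = freqs),
              collapse = "")
      }, character(1))
      tibble(
        id = sprintf("%s_%03d", tag, seq_len(n)),
        description = sprintf("synthetic %s PrLD", cls),
        sequence = seqs,
        label = cls
      )
    }
    dplyr::bind_rows(draw_class("positive", as.integer(n_pos), "pos"),
                     draw_class("negative", as.integer(n_neg), "neg"))
  })
}
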