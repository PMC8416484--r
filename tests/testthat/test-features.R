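test_that("window profile matches the brute-force oracle", {
  # hand-checkable case: window 3 with asymmetric values, truncated ends
  scale <- toy_scale(K = 0, D = 3, E = -3)
  expect_equal(sg_window_profile("KDE", scale, 3), c(1.5, 0, 0))
  expect_equal(brute_profile("KDE", scale, 3), c(1.5, 0, 0))

  withr::with_seed(11, {
    for (i in 1:20) {
      seq <- random_sequence(sample(5:60, 1))
      scale <- setNames(round(runif(20, -3, 3), 2), AA20)
      window <- sample(c(1, 3, 5), 1)
      expect_equal(sg_window_profile(seq, scale, window),
                   brute_profile(seq, scale, window))
    }
  })
})

test_that("window-1 profile is the raw scale and uniform scales are flat", {
  withr::with_seed(3, {
    scale <- setNames(runif(20, -2, 2), AA20)
    seq <- random_sequence(30)
    expect_equal(sg_window_profile(seq, scale, 1),
                 unname(scale[strsplit(seq, "")[[1]]]))
    for (w in c(1, 3, 7)) {
      expect_equal(sg_window_profile(seq, uniform_scale(0.7), w),
                   rep(0.7, 30))
    }
  })
})

test_that("window parameters are validated", {
  expect_error(sg_window_profile("MKQDE", uniform_scale(), 4),
               class = "sgpred_parameter_error")
  expect_error(sg_window_profile("MKQDE", uniform_scale(), -1),
               class = "sgpred_parameter_error")
  expect_error(sg_window_profile("MKQ", uniform_scale(), 5),
               class = "sgpred_length_error")
})

test_that("Na4vSS is 100x the mean window-averaged propensity", {
  # uniform scale c => Na4vSS = 100c for any sequence and window
  withr::with_seed(4, {
    for (c_val in c(-1.2, 0, 0.5)) {
      for (w in c(1, 3, 5)) {
        expect_equal(sg_na4vss(random_sequence(40), uniform_scale(c_val), w),
                     100 * c_val)
      }
    }
    # direct-summation oracle on random cases
    for (i in 1:10) {
      seq <- random_sequence(25)
      scale <- setNames(runif(20, -3, 3), AA20)
      expect_equal(sg_na4vss(seq, scale, 5),
                   sum(brute_profile(seq, scale, 5)) / nchar(seq) * 100)
    }
  })
  expect_equal(sg_na4vss("KDE", toy_scale(K = 0, D = 3, E = -3), 3),
               (1.5 + 0 + 0) / 3 * 100)
})

test_that("Na4vSS normalization anchors, clamps and is monotone", {
  b <- sg_norm_bounds(-40, 10)
  expect_equal(sg_normalize_na4vss(-40, b), 0)
  expect_equal(sg_normalize_na4vss(10, b), 1)
  expect_equal(sg_normalize_na4vss(-15, b), 0.5)
  expect_equal(sg_normalize_na4vss(25, b), 1)
  expect_equal(sg_normalize_na4vss(-100, b), 0)
  raw <- sort(runif(50, -80, 40))
  expect_true(all(diff(sg_normalize_na4vss(raw, b)) >= 0))
  expect_error(sg_norm_bounds(5, 5), class = "sgpred_configuration_error")
})

test_that("Henderson-Hasselbalch charges follow the closed form", {
  pka <- sg_pka_table()
  expect_equal(sg_residue_charge("G", 7), 0)
  expect_equal(sg_residue_charge("A", 2), 0)
  # half-dissociation at pH == pKa, both polarities
  expect_equal(sg_residue_charge("D", pH = pka$pka[["D"]]), -0.5)
  expect_equal(sg_residue_charge("K", pH = pka$pka[["K"]]), 0.5)
  # high-precision spot value: K at pH 7, pKa 10.53
  expect_equal(sg_residue_charge("K", 7), 1 / (1 + 10^(7 - 10.53)),
               tolerance = 1e-12)
  expect_equal(sg_residue_charge("K", 7), 0.99971, tolerance = 1e-4)
  expect_error(sg_residue_charge("X", 7), class = "sgpred_invalid_residue")
})

test_that("NCPR sums per-residue charges and honors termini flag", {
  expect_equal(sg_ncpr("GGGG", 7), 0)
  expect_equal(sg_ncpr("KKKK", 7), 1 / (1 + 10^(7 - 10.53)))
  expect_equal(sg_ncpr("KD", 7),
               (sg_residue_charge("K", 7) + sg_residue_charge("D", 7)) / 2)
  pka <- sg_pka_table()
  with_term <- sg_ncpr("GGGG", 7, include_termini = TRUE)
  expect_equal(with_term,
               (1 / (1 + 10^(7 - pka$nterm_pka)) -
                  1 / (1 + 10^(pka$cterm_pka - 7))) / 4)
})

test_that("NCPR is a composition-only quantity within (-1, 1)", {
  withr::with_seed(9, {
    for (i in 1:15) {
      seq <- random_sequence(sample(10:80, 1))
      perm <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
      expect_equal(sg_ncpr(seq), sg_ncpr(perm))
      expect_gt(sg_ncpr(seq), -1)
      expect_lt(sg_ncpr(seq), 1)
    }
  })
})

test_that("cysteine percentage counts composition", {
  expect_equal(sg_cys_pct("CCCCC"), 100)
  expect_equal(sg_cys_pct("GGGG"), 0)
  expect_equal(sg_cys_pct("CGGGGGGGGG"), 10)
  withr::with_seed(2, {
    for (i in 1:15) {
      seq <- random_sequence(sample(5:100, 1))
      pct <- sg_cys_pct(seq)
      expect_gte(pct, 0)
      expect_lte(pct, 100)
      expect_equal(pct == 0, !grepl("C", seq))
    }
  })
})

test_that("appending the most aggregation-prone residue never lowers mean a3v", {
  withr::with_seed(13, {
    scale <- setNames(runif(20, -3, 3), AA20)
    top <- names(scale)[which.max(scale)]
    for (i in 1:10) {
      seq <- random_sequence(sample(5:50, 1))
      res <- strsplit(seq, "")[[1]]
      expect_gte(mean(scale[c(res, top)]), mean(scale[res]))
    }
  })
})

test_that("featurize agrees with the three feature operations composed", {
  cfg <- sg_feature_config(bounds = sg_norm_bounds(-50, 10))
  data <- tibble::tibble(
    id = c("a", "b"),
    sequence = c(random_sequence(40), random_sequence(120))
  )
  feats <- sg_featurize(data, cfg)
  for (i in 1:2) {
    w <- if (nchar(data$sequence[i]) <= 75) 5 else 7
    expect_equal(feats$agg_raw[i],
                 sg_na4vss(data$sequence[i], cfg$scale, w))
    expect_equal(feats$agg_norm[i],
                 sg_normalize_na4vss(feats$agg_raw[i], cfg$bounds))
    expect_equal(feats$ncpr[i], sg_ncpr(data$sequence[i], cfg$pH, cfg$pka))
    expect_equal(feats$cys_pct[i], sg_cys_pct(data$sequence[i]))
  }
  # determinism
  expect_identical(feats, sg_featurize(data, cfg))
  # poly-G under a zero scale
  pg <- sg_featurize(tibble::tibble(id = "g", sequence = strrep("G", 20)),
                     sg_feature_config(scale = uniform_scale(0),
                                       bounds = sg_norm_bounds(-1, 1)))
  expect_equal(pg$agg_raw, 0)
  expect_equal(pg$ncpr, 0)
  expect_equal(pg$cys_pct, 0)
})

test_that("sequences below the minimum scoring window are rejected", {
  expect_error(
    sg_featurize(tibble::tibble(id = "short", sequence = "MKQ"),
                 sg_feature_config()),
    class = "sgpred_length_error"
  )
})

test_that("default scale and pKa files parse and validate", {
  scale <- sg_propensity_scale()
  expect_length(scale, 20)
  expect_setequal(names(scale), AA20)
  # direction sanity: aliphatic/aromatic residues above Q/N/charged
  expect_gt(min(scale[c("I", "F", "V", "L")]), max(scale[c("Q", "N", "D", "E", "K", "R")]))
  pka <- sg_pka_table()
  expect_true(all(c("D", "E", "C", "Y", "H", "K", "R") %in% names(pka$pka)))
  expect_true(all(pka$pka > 0 & pka$pka < 14))
})
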