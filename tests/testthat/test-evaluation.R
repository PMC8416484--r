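test_that("confusion counts partition the predictions", {
  all_pos <- rep("positive", 5)
  expect_equal(sg_confusion(all_pos, all_pos),
               tibble::tibble(tp = 5L, fp = 0L, tn = 0L, fn = 0L),
               ignore_attr = TRUE)
  expect_equal(sg_confusion(all_pos, rep("negative", 5))$fn, 5L)
  expect_error(sg_confusion(all_pos, all_pos[1:3]),
               class = "sgpred_input_error")

  # the held-out-set composition: 14 concordant positives, 16 concordant
  # negatives, 2 missed positives
  truth <- c(rep("positive", 16), rep("negative", 16))
  pred <- c(rep("positive", 14), rep("negative", 2), rep("negative", 16))
  cc <- sg_confusion(truth, pred)
  expect_equal(unlist(cc), c(tp = 14L, fp = 0L, tn = 16L, fn = 2L))
})

test_that("metrics implement the six printed formulas with NA for 0/0", {
  m <- sg_metrics(tp = 14, tn = 16, fn = 2, fp = 0)
  expect_equal(m$sensitivity, 14 / 16)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$accuracy, 30 / 32)
  expect_equal(m$f1, 14 / 15)
  expect_equal(m$mcc, 224 / sqrt(14 * 16 * 16 * 18))

  perfect <- sg_metrics(tp = 7, tn = 9, fp = 0, fn = 0)
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  precision = 1, accuracy = 1, f1 = 1, mcc = 1))

  undef <- sg_metrics(tp = 0, fp = 0, tn = 4, fn = 3)
  expect_true(is.na(undef$precision))
  expect_true(is.na(undef$mcc))
  expect_false(is.na(undef$accuracy))
})

test_that("metrics are invariant to reordering of the pairs", {
  withr::with_seed(6, {
    truth <- sample(c("positive", "negative"), 30, replace = TRUE)
    truth[1:2] <- c("positive", "negative")
    pred <- sample(c("positive", "negative"), 30, replace = TRUE)
    perm <- sample(30)
    expect_equal(sg_metrics(sg_confusion(truth, pred)),
                 sg_metrics(sg_confusion(truth[perm], pred[perm])))
  })
})

test_that("ROC endpoints, monotonicity and canonical AUCs hold", {
  truth <- c(rep("positive", 3), rep("negative", 3))
  perfect <- sg_roc(c(3, 2.5, 2, 1, 0.5, 0), truth)
  expect_equal(perfect$auc, 1)
  flat <- sg_roc(rep(0.4, 6), truth)
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$points), 2)

  r <- sg_roc(c(3, 1, 1, 2, 1, 0), truth)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(sg_roc(1:3, rep("positive", 3)),
               class = "sgpred_degenerate_error")
})

test_that("trapezoidal AUC equals the pairwise U oracle, ties included", {
  # the spec-level identity AUC = U / (n1 * n2) on random small instances
  withr::with_seed(17, {
    for (i in 1:40) {
      n1 <- sample(1:6, 1)
      n2 <- sample(1:6, 1)
      truth <- c(rep("positive", n1), rep("negative", n2))
      scores <- sample(seq(0, 2, by = 0.5), n1 + n2, replace = TRUE)
      r <- sg_roc(scores, truth)
      expect_equal(r$auc, pairwise_auc(scores, truth))
      u <- sg_mann_whitney(scores[truth == "positive"],
                           scores[truth == "negative"])$u
      expect_equal(r$auc, u / (n1 * n2))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    truth <- c(rep("positive", 12), rep("negative", 12))
    scores <- c(rnorm(12, 1), rnorm(12))
    r <- sg_roc(scores, truth)
    ref <- pROC::auc(pROC::roc(response = truth, predictor = scores,
                               levels = c("negative", "positive"),
                               direction = "<", quiet = TRUE))
    expect_equal(r$auc, as.numeric(ref))
  })
})

test_that("Mann-Whitney U identities and the enumerated example hold", {
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- sample(1:5, sample(2:5, 1), replace = TRUE)
      y <- sample(1:5, sample(2:5, 1), replace = TRUE)
      expect_equal(sg_mann_whitney(x, y)$u + sg_mann_whitney(y, x)$u,
                   length(x) * length(y))
    }
  })
  # full enumeration of the 6 assignments of {1,2,3,4} into two pairs
  res <- sg_mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$method, "exact")
  # identical multisets: U = n^2 / 2
  same <- sg_mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$u, 9 / 2)
  expect_error(sg_mann_whitney(numeric(0), 1), class = "sgpred_input_error")
})

test_that("exact and normal Mann-Whitney p-values agree within a sanity band", {
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- rnorm(6)
      y <- rnorm(6, 0.5)
      p_exact <- sg_mann_whitney(x, y)$p_value
      p_norm <- sg_mann_whitney(x, y, exact_limit = 0)$p_value
      expect_lt(abs(p_exact - p_norm), 0.05)
    }
  })
})

test_that("large-sample Mann-Whitney matches wilcox.test", {
  withr::with_seed(43, {
    x <- rnorm(20)
    y <- rnorm(25, 0.7)
    ours <- sg_mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$method, "normal")
    # wilcox.test's W for x is the same U statistic
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("stratified split is exact, disjoint and seeded", {
  sim <- sg_simulate(n_pos = 32, n_neg = 32, seed = 2)
  halves <- sg_split(sim, fraction = 0.5, seed = 10)
  expect_equal(sum(halves$train$label == "positive"), 16)
  expect_equal(sum(halves$train$label == "negative"), 16)
  expect_equal(sum(halves$test$label == "positive"), 16)
  expect_equal(sum(halves$test$label == "negative"), 16)
  expect_length(intersect(halves$train$id, halves$test$id), 0)
  expect_setequal(c(halves$train$id, halves$test$id), sim$id)

  expect_identical(halves, sg_split(sim, fraction = 0.5, seed = 10))
  expect_false(identical(halves, sg_split(sim, fraction = 0.5, seed = 11)))

  # rounding half up per class: 5 positives at 0.5 -> 3 in training
  odd <- sg_simulate(n_pos = 5, n_neg = 4, seed = 1)
  h2 <- sg_split(odd, 0.5, seed = 1)
  expect_equal(sum(h2$train$label == "positive"), 3)
  expect_equal(sum(h2$train$label == "negative"), 2)

  tiny <- sg_simulate(n_pos = 1, n_neg = 4, seed = 1)
  expect_error(sg_split(tiny, 0.5, seed = 1), class = "sgpred_split_error")
})

test_that("evaluate_predictor composes confusion, metrics and ROC", {
  sim <- sg_simulate(n_pos = 12, n_neg = 12, seed = 4)
  halves <- sg_split(sim, 0.5, seed = 4)
  fit <- sg_fit(halves$train, seed = 4)
  ev <- sg_evaluate(fit, halves$test)
  preds <- predict(fit, halves$test)
  expect_equal(ev$confusion, sg_confusion(halves$test$label, preds$prediction))
  expect_equal(ev$metrics, sg_metrics(ev$confusion))
  expect_equal(ev$roc$auc, sg_roc(preds$score, halves$test$label)$auc)
  expect_gte(ev$metrics$accuracy, 0.85)
  g <- glance(ev)
  expect_true(all(c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
                    "precision", "accuracy", "f1", "mcc", "auc") %in% names(g)))
})
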