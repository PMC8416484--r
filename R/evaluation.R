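#' Confusion counts for binary recruitment labels
#'
#' @param truth,predicted Character vectors of `positive`/`negative` labels
#'   of equal length; `positive` means recruited into stress-granule foci.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn` summing to
#'   the number of pairs.
#' @export
sg_confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1L) {
    abort("`truth` and `predicted` must be non-empty and of equal length.",
          class = "sgpred_input_error")
  }
  assert_labels(truth, "truth")
  assert_labels(predicted, "predicted")
  tibble(
    tp = sum(truth == "positive" & predicted == "positive"),
    fp = sum(truth == "negative" & predicted == "positive"),
    tn = sum(truth == "negative" & predicted == "negative"),
    fn = sum(truth == "positive" & predicted == "negative")
  )
}

#' The six binary-classification performance metrics
#'
#' Computes, verbatim from the confusion counts:
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' precision = TP/(TP+FP); accuracy = (TP+TN)/(TP+TN+FP+FN);
#' F1 = TP/(TP + (FP+FN)/2); and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is undefined and reported as `NA`
#' (never coerced to 0 and never an error).
#'
#' @param counts A one-row data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (see [sg_confusion()]), or four non-negative scalars via `...`.
#' @param ... Alternatively `tp`, `fp`, `tn`, `fn` as named numbers.
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `f1`, `mcc`.
#' @examples
#' sg_metrics(tp = 14, tn = 16, fn = 2, fp = 0)
#' @export
sg_metrics <- function(counts = NULL, ...) {
  if (is.null(counts)) counts <- tibble(...)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- as.numeric(counts$tp[1]); fp <- as.numeric(counts$fp[1])
  tn <- as.numeric(counts$tn[1]); fn <- as.numeric(counts$fn[1])
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn < 1) {
    abort("Counts must be non-negative and sum to at least 1.",
          class = "sgpred_input_error")
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    f1 = ratio(tp, tp + (fp + fn) / 2),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(mcc_den)
  )
}

#' ROC curve and AUC from raw classifier scores
#'
#' Sweeps the decision threshold over the unique scores in descending order
#' (tied scores form a single step), plotting the true-positive rate against
#' the false-positive rate, and integrates the area under the curve by the
#' trapezoidal rule. The resulting AUC equals the Mann-Whitney
#' U statistic divided by `n_pos * n_neg`, counting ties as one half.
#'
#' @param scores Numeric classifier scores, larger meaning more
#'   positive-like.
#' @param truth Character `positive`/`negative` labels; both classes must be
#'   present.
#' @return An object of class `sg_roc`: list with a `points` tibble
#'   (`threshold`, `fpr`, `tpr`) beginning at (0, 0) and ending at (1, 1),
#'   and the scalar `auc`.
#' @export
sg_roc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    abort("`scores` and `truth` must have equal length.",
          class = "sgpred_input_error")
  }
  assert_labels(truth, "truth")
  n_pos <- sum(truth == "positive")
  n_neg <- sum(truth == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC analysis requires both classes in `truth`.",
          class = "sgpred_degenerate_error")
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("`scores` must be finite.", class = "sgpred_input_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == "positive"),
                numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == "negative"),
                numeric(1)) / n_neg
  points <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "sg_roc")
}

#' @export
print.sg_roc <- function(x, ...) {
  cat(sprintf("<sg_roc> %d positive vs %d negative, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @rdname sg_roc
#' @param x An `sg_roc`.
#' @param ... Unused.
#' @method tidy sg_roc
#' @export
tidy.sg_roc <- function(x, ...) x$points

#' @rdname sg_roc
#' @method glance sg_roc
#' @export
glance.sg_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method autoplot sg_roc
#' @export
autoplot.sg_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(color = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-based two-sample comparison. U is computed from rank sums with
#' midrank ties. The two-tailed p-value comes from exact enumeration of all
#' group assignments of the pooled values when the combined sample size is
#' at most `exact_limit`, and otherwise from the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Combined sample size up to which the exact
#'   enumeration is used (default 12).
#' @return A one-row tibble with columns `u` (statistic of `x`),
#'   `p_value` (two-tailed), `method` (`"exact"` or `"normal"`),
#'   `n1`, `n2`. The swapped statistic satisfies `U + U' = n1 * n2`.
#' @export
sg_mann_whitney <- function(x, y, exact_limit = 12L) {
  if (length(x) < 1L || length(y) < 1L) {
    abort("Both samples must be non-empty.", class = "sgpred_input_error")
  }
  n1 <- length(x); n2 <- length(y)
  u_obs <- mw_u(x, y)
  if (n1 + n2 <= exact_limit) {
    p <- mw_exact_p(c(x, y), n1, u_obs)
    method <- "exact"
  } else {
    p <- mw_normal_p(c(x, y), n1, n2, u_obs)
    method <- "normal"
  }
  tibble(u = u_obs, p_value = min(max(p, .Machine$double.xmin), 1),
         method = method, n1 = n1, n2 = n2)
}

# U of the first sample: rank-sum form with midranks,
# U = R1 - n1(n1+1)/2 = #{x > y} + #{x == y}/2.
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-tailed p: enumerate every assignment of n1 of the pooled values
# to the first group; two-tailed by doubling-free symmetry around n1*n2/2.
mw_exact_p <- function(pooled, n1, u_obs) {
  n <- length(pooled)
  r <- rank(pooled)
  idx <- combn(n, n1)
  us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  center <- n1 * (n - n1) / 2
  dev <- abs(u_obs - center)
  mean(abs(us - center) >= dev - 1e-9)
}

# Normal approximation with tie correction and continuity correction.
mw_normal_p <- function(pooled, n1, n2, u_obs) {
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  if (u_obs == mu) z <- 0
  2 * pnorm(-abs(z))
}

#' Stratified train/test split
#'
#' Randomly partitions a labeled dataset class by class: each class
#' contributes `round(n * fraction)` records (rounding half up) to the
#' training half and the remainder to the test half. With 32 positives and
#' 32 negatives at the default fraction of 0.5 this yields the 16+16 /
#' 16+16 design used for training and held-out testing.
#'
#' @param data A labeled tibble with columns `id`, `sequence`, `label`.
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with tibbles `train` and `test`: disjoint, and their union
#'   is the input dataset.
#' @export
sg_split <- function(data, fraction = 0.5, seed = 1L) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  assert_labels(data$label)
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.",
          class = "sgpred_parameter_error")
  }
  idx_train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(CLASS_LEVELS, function(cls) {
      rows <- which(data$label == cls)
      if (length(rows) == 0L) return(integer(0))
      k <- floor(length(rows) * fraction + 0.5)
      if (k < 1L || k >= length(rows)) {
        abort(sprintf(
          "Class '%s' (n = %d) cannot yield non-empty train and test halves at fraction %.2f.",
          cls, length(rows), fraction), class = "sgpred_split_error")
      }
      sample(rows, k)
    }))
  })
  idx_train <- sort(idx_train)
  list(train = as_tibble(data[idx_train, , drop = FALSE]),
       test = as_tibble(data[-idx_train, , drop = FALSE]))
}

#' Evaluate a fitted predictor on a labeled test set
#'
#' Classifies every record, assembles confusion counts, the six performance
#' metrics and the ROC curve from the raw network scores.
#'
#' @param bundle An `sg_predictor`.
#' @param data A labeled tibble with columns `id`, `sequence`, `label`.
#' @return An object of class `sg_evaluation`: list with `predictions`
#'   (per-record tibble), `confusion`, `metrics` and `roc`.
#' @export
sg_evaluate <- function(bundle, data) {
  stopifnot(inherits(bundle, "sg_predictor"), "label" %in% names(data))
  assert_labels(data$label)
  preds <- predict(bundle, data)
  counts <- sg_confusion(data$label, preds$prediction)
  roc <- if (length(unique(data$label)) == 2L)
    sg_roc(preds$score, data$label) else NULL
  structure(
    list(predictions = preds, confusion = counts,
         metrics = sg_metrics(counts), roc = roc),
    class = "sg_evaluation"
  )
}

#' @export
print.sg_evaluation <- function(x, ...) {
  cat("<sg_evaluation>\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn, x$confusion$fn))
  m <- x$metrics
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f  MCC %.3f\n",
              m$sensitivity, m$specificity, m$accuracy, m$mcc))
  if (!is.null(x$roc)) cat(sprintf("  AUC %.4f\n", x$roc$auc))
  invisible(x)
}

#' @rdname sg_evaluate
#' @param x An `sg_evaluation`.
#' @param ... Unused.
#' @method tidy sg_evaluation
#' @export
tidy.sg_evaluation <- function(x, ...) x$predictions

#' @rdname sg_evaluate
#' @method glance sg_evaluation
#' @export
glance.sg_evaluation <- function(x, ...) {
  dplyr::bind_cols(x$confusion, x$metrics,
                   tibble(auc = if (is.null(x$roc)) NA_real_ else x$roc$auc))
}
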