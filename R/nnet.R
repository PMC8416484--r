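#' Training configuration for gdx backpropagation
#'
#' Settings for batch gradient descent with momentum and an adaptive
#' learning rate. After each epoch the new sum-of-squared-errors E is
#' compared with the previous one: a step that worsens E by more than a
#' factor `max_perf_inc` is rejected (weights reverted, learning rate
#' multiplied by `lr_dec`); an accepted step that improves E multiplies the
#' learning rate by `lr_inc`. Defaults are the canonical settings of this
#' algorithm family.
#'
#' @param epochs Maximum number of epochs.
#' @param goal Target sum of squared errors; training stops once reached.
#' @param lr0 Initial learning rate.
#' @param lr_inc Learning-rate increase factor (> 1).
#' @param lr_dec Learning-rate decrease factor (< 1).
#' @param max_perf_inc Tolerated error-increase ratio (> 1) before a step is
#'   rejected.
#' @param momentum Momentum coefficient in \[0, 1).
#' @return An object of class `sg_train_config`.
#' @export
sg_train_config <- function(epochs = 500L, goal = 0.01, lr0 = 0.01,
                            lr_inc = 1.05, lr_dec = 0.7,
                            max_perf_inc = 1.04, momentum = 0.9) {
  if (!(lr_dec < 1 && lr_inc > 1 && max_perf_inc > 1)) {
    abort("Require lr_dec < 1 < lr_inc and max_perf_inc > 1.",
          class = "sgpred_parameter_error")
  }
  if (momentum < 0 || momentum >= 1) {
    abort("`momentum` must lie in [0, 1).", class = "sgpred_parameter_error")
  }
  structure(list(epochs = as.integer(epochs), goal = goal, lr0 = lr0,
                 lr_inc = lr_inc, lr_dec = lr_dec,
                 max_perf_inc = max_perf_inc, momentum = momentum),
            class = "sg_train_config")
}

#' Initialize a multilayer perceptron
#'
#' Creates the 3-9-6-1 feed-forward network used for recruitment
#' classification (sizes configurable): hyperbolic-tangent units in every
#' layer, weights and biases drawn uniformly from \[-0.5, 0.5\] by a seeded
#' generator, per-feature input scaling initialized to the identity, and a
#' decision threshold of 0 on the output activation.
#'
#' @param seed Integer seed; identical seeds give bitwise-identical models.
#' @param layer_sizes Integer vector of layer widths, inputs first.
#' @return An object of class `sg_mlp`.
#' @export
sg_init_model <- function(seed, layer_sizes = c(3L, 9L, 6L, 1L)) {
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L))
  n_in <- layer_sizes[1]
  withr::with_seed(as.integer(seed), {
    weights <- list()
    biases <- list()
    for (l in seq_len(length(layer_sizes) - 1L)) {
      weights[[l]] <- matrix(runif(layer_sizes[l + 1] * layer_sizes[l],
                                   -0.5, 0.5),
                             nrow = layer_sizes[l + 1])
      biases[[l]] <- runif(layer_sizes[l + 1], -0.5, 0.5)
    }
    structure(
      list(layer_sizes = as.integer(layer_sizes),
           weights = weights, biases = biases,
           activation = "tanh",
           input_scaling = list(center = rep(0, n_in), gain = rep(1, n_in)),
           decision_threshold = 0),
      class = "sg_mlp"
    )
  })
}

#' @export
print.sg_mlp <- function(x, ...) {
  cat("<sg_mlp> ", paste(x$layer_sizes, collapse = "-"),
      " tanh network, decision threshold ", x$decision_threshold, "\n",
      sep = "")
  invisible(x)
}

scale_inputs <- function(model, X) {
  sweep(sweep(X, 2, model$input_scaling$center, "-"),
        2, model$input_scaling$gain, "*")
}

# Forward pass over a batch; returns activations per layer (inputs first)
# for reuse in backpropagation. X is n x n_in.
mlp_forward_full <- function(model, X) {
  A <- t(scale_inputs(model, X))
  acts <- list(A)
  for (l in seq_along(model$weights)) {
    A <- tanh(model$weights[[l]] %*% A + model$biases[[l]])
    acts[[l + 1L]] <- A
  }
  acts
}

#' Network output score for feature vectors
#'
#' Applies the input-scaling layer and the tanh activation chain; for a tanh
#' output unit the score lies in (-1, 1), with positive scores indicating
#' predicted recruitment.
#'
#' @param model An `sg_mlp`.
#' @param X A numeric matrix (rows = sequences, columns = the three
#'   features) or a single feature vector.
#' @return Numeric vector of raw network scores.
#' @export
sg_forward <- function(model, X) {
  stopifnot(inherits(model, "sg_mlp"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1]) {
    abort(sprintf("Expected %d input feature(s), got %d.",
                  model$layer_sizes[1], ncol(X)),
          class = "sgpred_input_error")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    abort("Feature values must be finite.", class = "sgpred_input_error")
  }
  acts <- mlp_forward_full(model, X)
  as.numeric(acts[[length(acts)]])
}

#' Binary classification from network scores
#'
#' @inheritParams sg_forward
#' @return A tibble with columns `score` and `label`; a score greater than
#'   or equal to the model's decision threshold (ties included) is labelled
#'   `positive`.
#' @export
sg_classify <- function(model, X) {
  score <- sg_forward(model, X)
  tibble(score = score,
         label = ifelse(score >= model$decision_threshold,
                        "positive", "negative"))
}

# Backpropagated gradient of the batch SSE, E = sum_i (y_i - t_i)^2,
# with tanh'(z) = 1 - a^2. Returns gradients shaped like weights/biases.
mlp_gradient <- function(model, X, target) {
  acts <- mlp_forward_full(model, X)
  L <- length(model$weights)
  out <- acts[[L + 1L]]
  delta <- 2 * (out - matrix(target, nrow = 1)) * (1 - out^2)
  gw <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gw[[l]] <- delta %*% t(acts[[l]])
    gb[[l]] <- rowSums(delta)
    if (l > 1L) {
      delta <- (t(model$weights[[l]]) %*% delta) * (1 - acts[[l]]^2)
    }
  }
  list(weights = gw, biases = gb)
}

mlp_sse <- function(model, X, target) {
  sum((sg_forward(model, X) - target)^2)
}

encode_targets <- function(label) {
  assert_labels(label)
  ifelse(label == "positive", 1, -1)
}

#' Train a network by gradient descent with momentum and adaptive learning rate
#'
#' Batch backpropagation minimizing the sum of squared errors between tanh
#' outputs and -1/+1 class targets. Per epoch, the velocity update is
#' `V <- momentum * V - (1 - momentum) * lr * gradient`, applied to all
#' weights and biases; the adaptive rule then accepts or rejects the step on
#' the new error (see [sg_train_config()]). On rejection the velocity is
#' reset. Training is deterministic given the initial model and data.
#'
#' @param model An `sg_mlp` (see [sg_init_model()]).
#' @param X Numeric feature matrix, one row per training sequence.
#' @param label Character vector of `positive`/`negative` truth labels; both
#'   classes must be present.
#' @param config An [sg_train_config()].
#' @return A list with the trained `model` and a `report` of class
#'   `sg_train_report` (per-epoch error trace, final learning rate, stop
#'   reason).
#' @export
sg_train_gdx <- function(model, X, label, config = sg_train_config()) {
  stopifnot(inherits(model, "sg_mlp"), inherits(config, "sg_train_config"))
  if (is.null(dim(X))) X <- matrix(X, ncol = model$layer_sizes[1])
  X <- as.matrix(X)
  if (nrow(X) != length(label) || nrow(X) < 2L) {
    abort("Need one label per row of `X` and at least two samples.",
          class = "sgpred_input_error")
  }
  target <- encode_targets(label)
  if (length(unique(label)) < 2L) {
    abort("Training requires both classes to be present.",
          class = "sgpred_degenerate_training")
  }
  lr <- config$lr0
  vel_w <- lapply(model$weights, function(w) w * 0)
  vel_b <- lapply(model$biases, function(b) b * 0)
  E_old <- mlp_sse(model, X, target)
  trace <- numeric(config$epochs)
  stop_reason <- "epochs exhausted"
  n_epochs <- 0L
  for (epoch in seq_len(config$epochs)) {
    grad <- mlp_gradient(model, X, target)
    for (l in seq_along(model$weights)) {
      vel_w[[l]] <- config$momentum * vel_w[[l]] -
        (1 - config$momentum) * lr * grad$weights[[l]]
      vel_b[[l]] <- config$momentum * vel_b[[l]] -
        (1 - config$momentum) * lr * grad$biases[[l]]
    }
    cand <- model
    for (l in seq_along(model$weights)) {
      cand$weights[[l]] <- model$weights[[l]] + vel_w[[l]]
      cand$biases[[l]] <- model$biases[[l]] + vel_b[[l]]
    }
    E_new <- mlp_sse(cand, X, target)
    if (!is.finite(E_new)) {
      abort(sprintf("Training diverged (non-finite error) at epoch %d.", epoch),
            class = "sgpred_divergence_error")
    }
    if (E_new > E_old * config$max_perf_inc) {
      # reject: keep weights, shrink the learning rate, drop the velocity
      lr <- lr * config$lr_dec
      vel_w <- lapply(vel_w, function(v) v * 0)
      vel_b <- lapply(vel_b, function(v) v * 0)
    } else {
      if (E_new < E_old) lr <- lr * config$lr_inc
      model <- cand
      E_old <- E_new
    }
    trace[epoch] <- E_old
    n_epochs <- epoch
    if (E_old <= config$goal) {
      stop_reason <- "goal reached"
      break
    }
  }
  report <- structure(
    list(error_trace = trace[seq_len(n_epochs)], epochs = n_epochs,
         final_error = E_old, final_lr = lr, stop_reason = stop_reason),
    class = "sg_train_report"
  )
  list(model = model, report = report)
}

#' @export
print.sg_train_report <- function(x, ...) {
  cat(sprintf("<sg_train_report> %d epoch(s), final SSE %.5g (%s), final lr %.4g\n",
              x$epochs, x$final_error, x$stop_reason, x$final_lr))
  invisible(x)
}

#' @rdname sg_train_gdx
#' @param x An `sg_train_report`.
#' @param ... Unused.
#' @method tidy sg_train_report
#' @export
tidy.sg_train_report <- function(x, ...) {
  tibble(epoch = seq_along(x$error_trace), sse = x$error_trace)
}

#' @method autoplot sg_train_report
#' @export
autoplot.sg_train_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$sse)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Sum of squared errors",
                  title = "Training error trace") +
    ggplot2::theme_minimal()
}
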