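#' Fit the recruitment predictor on a labeled dataset
#'
#' The full training pipeline: computes the three features for every
#' training sequence, derives the Na4vSS normalization bounds (min and max
#' raw score over the training set) and the per-feature input scaling to
#' \[-1, 1\], initializes a seeded network and trains it with gdx
#' backpropagation. The result is a self-contained bundle — network,
#' feature configuration and bounds — sufficient to classify new sequences.
#'
#' @param data A labeled tibble with columns `id`, `sequence`, `label`
#'   (see [sg_label_dataset()]).
#' @param feature_config An [sg_feature_config()]; any `bounds` it carries
#'   are ignored and re-derived from the training data.
#' @param train_config An [sg_train_config()].
#' @param seed Integer seed for weight initialization.
#' @param layer_sizes Network architecture, inputs first.
#' @return An object of class `sg_predictor`.
#' @examples
#' \donttest{
#' sim <- sg_simulate(n_pos = 16, n_neg = 16, seed = 1)
#' fit <- sg_fit(sim, seed = 1)
#' predict(fit, sim)
#' }
#' @export
sg_fit <- function(data, feature_config = sg_feature_config(),
                   train_config = sg_train_config(), seed = 1L,
                   layer_sizes = c(3L, 9L, 6L, 1L)) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  assert_labels(data$label)
  raw_cfg <- feature_config
  raw_cfg$bounds <- NULL
  feats <- sg_featurize(data, raw_cfg)
  bounds <- sg_norm_bounds(min(feats$agg_raw), max(feats$agg_raw))
  feature_config$bounds <- bounds
  feats$agg_norm <- sg_normalize_na4vss(feats$agg_raw, bounds)
  X <- feature_matrix(feats)
  model <- sg_init_model(seed, layer_sizes = layer_sizes)
  model$input_scaling <- derive_input_scaling(X)
  trained <- sg_train_gdx(model, X, data$label, train_config)
  structure(
    list(model = trained$model, feature_config = feature_config,
         bounds = bounds, train_report = trained$report,
         train_config = train_config, seed = as.integer(seed),
         n_train = nrow(data), version = BUNDLE_VERSION),
    class = "sg_predictor"
  )
}

# Per-feature affine map onto [-1, 1] from training min/max; a feature with
# zero range maps to the constant 0.
derive_input_scaling <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  gain <- ifelse(rng > 0, 2 / rng, 1)
  center <- (lo + hi) / 2
  list(center = unname(center), gain = unname(gain))
}

#' @export
print.sg_predictor <- function(x, ...) {
  cat("<sg_predictor> ", paste(x$model$layer_sizes, collapse = "-"),
      " tanh network trained on ", x$n_train, " sequence(s)\n", sep = "")
  cat(sprintf("  Na4vSS bounds: [%.3f, %.3f]; %s after %d epoch(s), SSE %.4g\n",
              x$bounds$na4vss_min, x$bounds$na4vss_max,
              x$train_report$stop_reason, x$train_report$epochs,
              x$train_report$final_error))
  invisible(x)
}

#' Predict stress-granule recruitment for new sequences
#'
#' @param object An `sg_predictor` from [sg_fit()] or [sg_load_model()].
#' @param newdata A tibble with columns `id` and `sequence`, or an
#'   already-featurized tibble carrying `agg_norm`, `ncpr`, `cys_pct`.
#' @param ... Unused.
#' @return `newdata` with columns `agg_raw`, `agg_norm`, `ncpr`, `cys_pct`,
#'   `score` and `prediction` (`positive`/`negative`) appended.
#' @export
predict.sg_predictor <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  feats <- if (all(c("agg_norm", "ncpr", "cys_pct") %in% names(newdata)) &&
               !anyNA(newdata$agg_norm)) {
    as_tibble(newdata)
  } else {
    sg_featurize(newdata, object$feature_config)
  }
  cls <- sg_classify(object$model, feature_matrix(feats))
  feats$score <- cls$score
  feats$prediction <- cls$label
  feats
}

#' @rdname sg_fit
#' @param x An `sg_predictor`.
#' @param ... Unused.
#' @return For `tidy()`: one row per connection weight or bias, with columns
#'   `layer`, `from`, `to`, `term`, `estimate`.
#' @method tidy sg_predictor
#' @export
tidy.sg_predictor <- function(x, ...) {
  purrr::map_dfr(seq_along(x$model$weights), function(l) {
    w <- x$model$weights[[l]]
    b <- x$model$biases[[l]]
    dplyr::bind_rows(
      tibble(layer = l,
             from = rep(seq_len(ncol(w)), each = nrow(w)),
             to = rep(seq_len(nrow(w)), times = ncol(w)),
             term = "weight", estimate = as.numeric(w)),
      tibble(layer = l, from = NA_integer_, to = seq_along(b),
             term = "bias", estimate = b)
    )
  })
}

#' @rdname sg_fit
#' @method glance sg_predictor
#' @export
glance.sg_predictor <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    epochs = x$train_report$epochs,
    final_sse = x$train_report$final_error,
    stop_reason = x$train_report$stop_reason,
    na4vss_min = x$bounds$na4vss_min,
    na4vss_max = x$bounds$na4vss_max,
    seed = x$seed
  )
}

BUNDLE_VERSION <- "sgpred-bundle/1"

#' Serialize a fitted predictor to JSON
#'
#' Writes the complete bundle — layer sizes, weights (row-major), biases,
#' input scaling, normalization bounds, feature configuration and training
#' settings — as a single versioned JSON document at full floating-point
#' precision, so a load/save round trip preserves predictions bit-exactly.
#'
#' @param bundle An `sg_predictor`.
#' @param path Optional output path; if `NULL` the JSON text is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
sg_save_model <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "sg_predictor"))
  fc <- bundle$feature_config
  doc <- list(
    version = BUNDLE_VERSION,
    layer_sizes = bundle$model$layer_sizes,
    weights = lapply(bundle$model$weights, function(w)
      list(nrow = nrow(w), ncol = ncol(w), data = as.numeric(t(w)))),
    biases = bundle$model$biases,
    activation = bundle$model$activation,
    input_scaling = bundle$model$input_scaling,
    decision_threshold = bundle$model$decision_threshold,
    bounds = unclass(bundle$bounds),
    feature_config = list(
      scale = as.list(fc$scale),
      window_bands = list(max_length = fc$window_bands[, 1],
                          window = fc$window_bands[, 2]),
      pH = fc$pH,
      pka = list(pka = as.list(fc$pka$pka),
                 polarity = as.list(fc$pka$polarity),
                 nterm_pka = fc$pka$nterm_pka,
                 cterm_pka = fc$pka$cterm_pka),
      include_termini = fc$include_termini
    ),
    train_config = unclass(bundle$train_config),
    train_report = unclass(bundle$train_report),
    n_train = bundle$n_train,
    seed = bundle$seed
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Load a serialized predictor
#'
#' @param path Path to a bundle written by [sg_save_model()], or the JSON
#'   text itself.
#' @return An `sg_predictor`.
#' @export
sg_load_model <- function(path) {
  txt <- if (length(path) == 1L && !grepl("[{\n]", path) && file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else
    paste(path, collapse = "\n")
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = TRUE),
    error = function(e) {
      abort(paste0("Cannot parse model bundle: ", conditionMessage(e)),
            class = "sgpred_load_error", parent = e)
    }
  )
  if (!identical(doc$version, BUNDLE_VERSION)) {
    abort(sprintf("Unsupported bundle version '%s' (expected '%s').",
                  doc$version %||% "<missing>", BUNDLE_VERSION),
          class = "sgpred_load_error")
  }
  required <- c("layer_sizes", "weights", "biases", "input_scaling",
                "bounds", "feature_config")
  if (!all(required %in% names(doc))) {
    abort("Corrupted model bundle: missing fields.", class = "sgpred_load_error")
  }
  weights <- if (is.data.frame(doc$weights)) {
    lapply(seq_len(nrow(doc$weights)), function(i)
      matrix(unlist(doc$weights$data[[i]]), nrow = doc$weights$nrow[i],
             ncol = doc$weights$ncol[i], byrow = TRUE))
  } else {
    lapply(doc$weights, function(w)
      matrix(unlist(w$data), nrow = w$nrow, ncol = w$ncol, byrow = TRUE))
  }
  biases <- if (is.list(doc$biases)) doc$biases else as.list(doc$biases)
  model <- structure(
    list(layer_sizes = as.integer(doc$layer_sizes),
         weights = weights,
         biases = lapply(biases, as.numeric),
         activation = doc$activation %||% "tanh",
         input_scaling = list(center = as.numeric(doc$input_scaling$center),
                              gain = as.numeric(doc$input_scaling$gain)),
         decision_threshold = doc$decision_threshold %||% 0),
    class = "sg_mlp"
  )
  fc_doc <- doc$feature_config
  feature_config <- sg_feature_config(
    scale = unlist(fc_doc$scale),
    window_bands = cbind(max_length = as.numeric(fc_doc$window_bands$max_length),
                         window = as.numeric(fc_doc$window_bands$window)),
    pH = fc_doc$pH,
    pka = list(pka = unlist(fc_doc$pka$pka),
               polarity = unlist(fc_doc$pka$polarity),
               nterm_pka = fc_doc$pka$nterm_pka,
               cterm_pka = fc_doc$pka$cterm_pka),
    include_termini = isTRUE(fc_doc$include_termini),
    bounds = sg_norm_bounds(doc$bounds$na4vss_min, doc$bounds$na4vss_max)
  )
  report <- if (!is.null(doc$train_report))
    structure(doc$train_report, class = "sg_train_report") else NULL
  tc <- if (!is.null(doc$train_config))
    structure(doc$train_config, class = "sg_train_config") else NULL
  structure(
    list(model = model, feature_config = feature_config,
         bounds = feature_config$bounds, train_report = report,
         train_config = tc, seed = doc$seed,
         n_train = doc$n_train, version = doc$version),
    class = "sg_predictor"
  )
}
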