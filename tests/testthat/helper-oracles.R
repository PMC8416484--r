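# Shared fixtures and independent oracles used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

uniform_scale <- function(value = 0) setNames(rep(value, 20), AA20)

# A toy scale that is zero everywhere except for chosen residues.
toy_scale <- function(...) {
  s <- uniform_scale(0)
  vals <- c(...)
  s[names(vals)] <- vals
  s
}

random_sequence <- function(len, residues = AA20) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

# Brute-force window-profile oracle: explicit loop, no cumulative sums.
brute_profile <- function(seq, scale, window) {
  res <- strsplit(seq, "")[[1]]
  half <- (window - 1) / 2
  vapply(seq_along(res), function(i) {
    idx <- max(1, i - half):min(length(res), i + half)
    mean(scale[res[idx]])
  }, numeric(1))
}

# Rank/pairwise AUC oracle: fraction of positive-negative pairs ranked
# correctly, ties counted one half.
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth == "positive"]
  neg <- scores[truth == "negative"]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Central finite-difference gradient of the batch SSE for an sg_mlp.
fd_gradient <- function(model, X, target, eps = 1e-6) {
  sse <- function(m) sgpred:::mlp_sse(m, X, target)
  gw <- lapply(model$weights, function(w) w * 0)
  gb <- lapply(model$biases, function(b) b * 0)
  for (l in seq_along(model$weights)) {
    for (j in seq_along(model$weights[[l]])) {
      up <- model; up$weights[[l]][j] <- up$weights[[l]][j] + eps
      dn <- model; dn$weights[[l]][j] <- dn$weights[[l]][j] - eps
      gw[[l]][j] <- (sse(up) - sse(dn)) / (2 * eps)
    }
    for (j in seq_along(model$biases[[l]])) {
      up <- model; up$biases[[l]][j] <- up$biases[[l]][j] + eps
      dn <- model; dn$biases[[l]][j] <- dn$biases[[l]][j] - eps
      gb[[l]][j] <- (sse(up) - sse(dn)) / (2 * eps)
    }
  }
  list(weights = gw, biases = gb)
}

# A tiny linearly separable 2-class feature problem in the 3-feature space.
separable_toy <- function() {
  X <- rbind(c(0.9, 0.05, 3), c(0.8, 0.08, 2),
             c(0.1, -0.05, 0), c(0.2, -0.02, 0.1))
  list(X = X, label = c("positive", "positive", "negative", "negative"))
}

tiny_labeled_dataset <- function() {
  tibble::tibble(
    id = c("p1", "p2", "n1", "n2"),
    description = "",
    sequence = c("MKIVLFCKEH", "IVLWFKKECH", "QQNNQGSYQN", "NQQSGYNNQS"),
    label = c("positive", "positive", "negative", "negative")
  )
}
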