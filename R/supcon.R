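#' Supervised contrastive loss configuration
#'
#' @param temperature Softmax temperature `tau` (> 0; default 0.07).
#' @param hard_scale Multiplier applied to the hardest negatives'
#'   denominator terms (>= 1; default 1.5).
#' @param hard_k Number of hardest negatives per anchor to scale
#'   (default 1).
#' @param hard_enabled Logical; enables hard-pair scaling (default TRUE).
#' @return An object of class `supcon_config`.
#' @export
supcon_config <- function(temperature = 0.07, hard_scale = 1.5, hard_k = 1,
                          hard_enabled = TRUE) {
  if (temperature <= 0) stopf("temperature must be positive")
  if (hard_scale < 1) stopf("hard_scale must be >= 1")
  if (hard_k < 0) stopf("hard_k must be >= 0")
  structure(list(temperature = temperature, hard_scale = hard_scale,
                 hard_k = as.integer(hard_k), hard_enabled = hard_enabled),
            class = "supcon_config")
}

check_projection_batch <- function(z, labels, tol = 1e-4) {
  if (!is.matrix(z) || nrow(z) < 2) stopf("need a batch of N >= 2 projections")
  if (length(labels) != nrow(z)) stopf("labels length must match batch size")
  norms <- sqrt(rowSums(z^2))
  if (any(abs(norms - 1) > tol))
    stopf("projection rows must be unit-norm (max deviation %.2e)",
          max(abs(norms - 1)))
  invisible(TRUE)
}

# Core computation behind supcon_loss()/hard_negative_adjust(): evaluates
# the multi-positive contrastive loss over unit-norm rows with optional
# hard-negative scaling of the denominator, and (optionally) its analytic
# gradient with respect to z. Log-sum-exp uses max-subtraction.
supcon_core <- function(z, labels, temperature, hard_scale = 1, hard_k = 0,
                        want_grad = FALSE) {
  n <- nrow(z)
  s <- tcrossprod(z) / temperature          # s[i, a] = sim(z_i, z_a) / tau
  same <- outer(labels, labels, `==`)
  loss <- 0
  G <- if (want_grad) matrix(0, n, n) else NULL
  for (i in seq_len(n)) {
    a_set <- setdiff(seq_len(n), i)
    p_set <- a_set[same[i, a_set]]
    if (length(p_set) == 0L) next         # singleton class: anchor skipped
    w <- rep(1, n)
    if (hard_scale > 1 && hard_k > 0) {
      negs <- a_set[!same[i, a_set]]
      if (length(negs) > 0L) {
        # hardest = highest cosine similarity; ties broken by lowest index
        ord <- negs[order(-s[i, negs], negs)]
        w[ord[seq_len(min(hard_k, length(ord)))]] <- hard_scale
      }
    }
    m <- max(s[i, a_set])
    terms <- w[a_set] * exp(s[i, a_set] - m)
    log_den <- m + log(sum(terms))
    loss <- loss + log_den - mean(s[i, p_set])
    if (want_grad) {
      soft <- numeric(n)
      soft[a_set] <- terms / sum(terms)
      soft[p_set] <- soft[p_set] - 1 / length(p_set)
      G[i, ] <- soft                       # dL_i / ds[i, a]
    }
  }
  out <- list(loss = loss)
  if (want_grad) out$dz <- (G %*% z + crossprod(G, z)) / temperature
  out
}

#' Multi-positive supervised contrastive loss
#'
#' For a batch of `N` unit-norm projections `z` with class labels, computes
#' \deqn{L = \sum_{i \in I} \frac{-1}{|P(i)|} \sum_{p \in P(i)}
#'   \log \frac{\exp(z_i \cdot z_p / \tau)}
#'             {\sum_{a \in A(i)} \exp(z_i \cdot z_a / \tau)}}
#' where `P(i)` are the same-label batch members excluding the anchor and
#' `A(i)` all members excluding the anchor (positives included in the
#' denominator, as the loss is printed). Anchors with no positives
#' contribute zero. Evaluation is numerically stabilized by
#' max-subtraction.
#'
#' @param z `N x p` matrix of unit-norm projections.
#' @param labels Length-`N` class labels (any atomic type).
#' @param config A [supcon_config()]; hard scaling is ignored here (see
#'   [hard_negative_adjust()]).
#' @return Nonnegative scalar loss, with attribute `"dz"` holding the
#'   analytic gradient w.r.t. `z` when `want_grad = TRUE`.
#' @param want_grad Logical; also compute the gradient.
#' @export
supcon_loss <- function(z, labels, config = supcon_config(),
                        want_grad = FALSE) {
  check_projection_batch(z, labels)
  res <- supcon_core(z, labels, config$temperature, hard_scale = 1,
                     hard_k = 0, want_grad = want_grad)
  out <- res$loss
  if (want_grad) attr(out, "dz") <- res$dz
  out
}

#' Supervised contrastive loss with hard-negative scaling
#'
#' As [supcon_loss()], but for each anchor the `hard_k` negatives with the
#' highest cosine similarity to the anchor have their denominator terms
#' `exp(sim/tau)` multiplied by `hard_scale` (similarity ties broken by
#' lowest index). With `hard_scale = 1` this reproduces [supcon_loss()]
#' bit-for-bit; with `hard_scale > 1` the loss is strictly larger whenever
#' any anchor has a negative. Anchors without negatives fall back to the
#' plain term.
#'
#' @inheritParams supcon_loss
#' @export
hard_negative_adjust <- function(z, labels, config = supcon_config(),
                                 want_grad = FALSE) {
  check_projection_batch(z, labels)
  hs <- if (isTRUE(config$hard_enabled)) config$hard_scale else 1
  res <- supcon_core(z, labels, config$temperature, hard_scale = hs,
                     hard_k = config$hard_k, want_grad = want_grad)
  out <- res$loss
  if (want_grad) attr(out, "dz") <- res$dz
  out
}

#' Combined training objective
#'
#' Sum (unit weights) of the supervised contrastive component on the
#' projections and the softmax cross-entropy component on the logits (mean
#' negative log-likelihood per sample). The logits are expected to come
#' from the gradient-detached classifier pathway of [dual_forward()].
#'
#' @param logits `N x 2` logit matrix.
#' @param z `N x p` unit-norm projection matrix.
#' @param labels Length-`N` class labels; for the cross-entropy term they
#'   are mapped to `{1, 2}` by first occurrence of sorted unique values
#'   (with `"HC"`/`"PD"`, PD is class 2).
#' @param config A [supcon_config()].
#' @return List with `total`, `supcon`, and `cross_entropy` components.
#' @export
combined_objective <- function(logits, z, labels, config = supcon_config()) {
  if (nrow(logits) != nrow(z) || nrow(logits) != length(labels))
    stopf("batch size mismatch between logits (%d), z (%d) and labels (%d)",
          nrow(logits), nrow(z), length(labels))
  sc <- hard_negative_adjust(z, labels, config)
  cls <- match(labels, sort(unique(labels)))
  ce <- softmax_ce(logits, cls)$loss
  list(total = as.numeric(sc) + ce, supcon = as.numeric(sc),
       cross_entropy = ce)
}
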