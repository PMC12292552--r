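#' Grad-CAM relevance map over a waveform
#'
#' Gradient-weighted class activation mapping taken at the output
#' projection of the final (selected) self-attention block: with
#' activations `A` (`T x d`) and channel weights `w_j` equal to the time
#' mean of the target logit's gradient w.r.t. `A`, the frame relevance is
#' `m_t = max(0, sum_j w_j A_tj)`, normalized to max 1 and linearly
#' interpolated to sample resolution. An identically-zero map is returned
#' as zeros with the `zero_map` flag set.
#'
#' @param model A [supcon_model()] whose encoder exposes the attention
#'   block cache (the bundled tiny encoder does).
#' @param clip A standardized [audio_clip()].
#' @param target_class `"PD"` or `"HC"`.
#' @return An object of class `relevance_map` with `frame_relevance`
#'   (length `T`, values in `[0, 1]`), `sample_relevance` (length equal to
#'   the waveform), `target_class` and `zero_map`.
#' @export
grad_cam_map <- function(model, clip, target_class = c("PD", "HC")) {
  target_class <- match.arg(target_class)
  stopifnot(inherits(clip, "audio_clip"))
  if (!inherits(model$encoder, "tiny_encoder"))
    stopf("encoder does not expose the attention output-projection hook")
  waves <- matrix(clip$samples, nrow = 1)
  enc <- encoder_forward(model$encoder, waves, want_cache = TRUE)
  clf <- classifier_fwd_cached(model$classifier, enc$emb, 0, FALSE)
  dlogits <- matrix(0, 1, 2)
  dlogits[1, if (target_class == "PD") 2 else 1] <- 1
  cb <- classifier_bwd(model$classifier, clf, dlogits)
  eb <- encoder_backward(model$encoder, enc, cb$demb)
  a_act <- enc$caches[[1]]$blocks[[enc$layer]]$att$out   # T x d activations
  d_act <- eb$hook_do[[1]]                               # T x d gradients
  w <- colMeans(d_act)
  m <- pmax(as.numeric(a_act %*% w), 0)
  zero_map <- max(m) == 0
  if (!zero_map) m <- m / max(m)
  stride <- model$encoder$stride
  centers <- (seq_along(m) - 0.5) * stride
  samp <- stats::approx(centers, m, xout = seq_along(clip$samples),
                        rule = 2)$y
  structure(list(frame_relevance = m, sample_relevance = samp,
                 target_class = target_class, zero_map = zero_map,
                 logits = clf$out[1, ]),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> target=%s frames=%d zero_map=%s\n",
              x$target_class, length(x$frame_relevance), x$zero_map))
  invisible(x)
}

#' 2-D stochastic neighbor embedding of learned representations
#'
#' Exact (O(N^2)) t-SNE: per-point Gaussian bandwidths found by binary
#' search to the target perplexity, symmetrized affinities, early
#' exaggeration, and momentum gradient descent with adaptive gains.
#' Deterministic given `seed`.
#'
#' @param embeddings `N x d` numeric matrix.
#' @param labels Optional length-`N` labels attached to the result.
#' @param seed Integer seed for the initial layout.
#' @param perplexity Target perplexity (default 30; auto-shrunk with a
#'   warning when `N < 3 * perplexity + 1`).
#' @param n_iter Gradient-descent iterations (default 500).
#' @return `N x 2` coordinate matrix with a `labels` attribute.
#' @export
embed_2d <- function(embeddings, labels = NULL, seed = 1, perplexity = 30,
                     n_iter = 500) {
  x <- as.matrix(embeddings)
  n <- nrow(x)
  if (n < 5) stopf("need at least 5 points for a 2-D embedding")
  if (n - 1 < 3 * perplexity) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning(sprintf("perplexity shrunk to %d for N=%d", perplexity, n),
            call. = FALSE)
  }
  sq <- rowSums(x^2)
  D <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
      p <- exp(-di * beta)
      sp <- sum(p)
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- with_seed(combine_seed(seed, "tsne"),
                 matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  vel <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  lr <- 100
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 12 else 1
    sqy <- rowSums(y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    vel <- mom * vel - lr * gains * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
  }
  attr(y, "labels") <- labels
  y
}
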