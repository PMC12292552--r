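#' Build a tiny trainable frame-level speech encoder
#'
#' A desk-scale stand-in for large self-supervised speech encoders that
#' honours the same contract: a fixed-length waveform in, a `T x d`
#' frame-embedding matrix out, with a selectable output layer. The front
#' end is a strided linear patch embedding (total stride 320 samples, the
#' 20 ms hop at 16 kHz) whose filters are initialized as a Hamming-windowed
#' mel-spaced cosine/sine filterbank, followed by half-wave rectification
#' and `log(1 + gain * x)` compression - the learnable analogue of a
#' log-mel front end - and then `n_layers` pre-norm single-head
#' self-attention blocks whose residual-branch output projections start
#' near zero (identity-preserving initialization), so the filterbank
#' features pass through unchanged at initialization and the attention
#' blocks fade in during training. Everything, including the filterbank, is
#' trainable. Initialization is deterministic in `seed`.
#'
#' @param d Embedding width (>= 8, even; large pre-trained encoders
#'   use 768).
#' @param n_layers Number of attention blocks (>= 1; default 2).
#' @param seed Integer seed for parameter initialization.
#' @param stride Front-end stride in samples (default 320).
#' @param sample_rate Sampling rate the filterbank initialization assumes
#'   (default 16000).
#' @param comp_gain Fixed gain inside the log compression (default 50).
#' @param prenorm_attention Logical; if TRUE each attention sublayer reads
#'   a layer-normalized copy of the residual stream (pre-norm). The
#'   default FALSE lets attention read the unnormalized stream, so frame
#'   energy is visible to the query/key comparison and the blocks can
#'   learn energy-selective (max-like) temporal pooling; the feed-forward
#'   sublayer stays pre-norm either way.
#' @return An object of class `tiny_encoder` with fields `params`, `d`,
#'   `n_layers`, `stride`, and the selected output `layer`
#'   (default `n_layers`).
#' @export
make_tiny_encoder <- function(d = 64, n_layers = 2, seed = 1, stride = 320L,
                              sample_rate = 16000, comp_gain = 50,
                              prenorm_attention = FALSE) {
  if (d < 8) stopf("encoder width d must be >= 8")
  if (n_layers < 1) stopf("n_layers must be >= 1")
  params <- with_seed(combine_seed(seed, "tiny-encoder"), {
    p <- list(conv = list(W = fourier_filterbank(stride, d, sample_rate),
                          b = rep(0, d)),
              blocks = lapply(seq_len(n_layers), function(i)
                init_block_params(d)))
    for (l in seq_len(n_layers)) {
      p$blocks[[l]]$attn$Wo <- p$blocks[[l]]$attn$Wo * 0.08
      p$blocks[[l]]$ffn$W2 <- p$blocks[[l]]$ffn$W2 * 0.08
      if (!prenorm_attention) {
        # moderate initial attention logits on the unnormalized stream
        p$blocks[[l]]$attn$Wq <- p$blocks[[l]]$attn$Wq * 0.2
        p$blocks[[l]]$attn$Wk <- p$blocks[[l]]$attn$Wk * 0.2
      }
    }
    p
  })
  structure(list(params = params, d = as.integer(d),
                 n_layers = as.integer(n_layers), stride = as.integer(stride),
                 comp_gain = comp_gain,
                 prenorm_attention = isTRUE(prenorm_attention),
                 layer = as.integer(n_layers)),
            class = "tiny_encoder")
}

# Hamming-windowed cosine/sine pairs at d/2 mel-spaced center frequencies:
# the front-end filterbank initialization. Small seeded jitter breaks exact
# phase symmetry between paired filters.
fourier_filterbank <- function(stride, d, sample_rate) {
  n_freq <- d %/% 2
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  freqs <- imel(seq(mel(40), mel(0.95 * sample_rate / 2),
                    length.out = n_freq))
  t_idx <- 0:(stride - 1)
  win <- 0.54 - 0.46 * cos(2 * pi * t_idx / (stride - 1))
  W <- matrix(0, stride, d)
  for (j in seq_len(n_freq)) {
    W[, 2 * j - 1] <- win * cos(2 * pi * freqs[j] * t_idx / sample_rate)
    W[, 2 * j] <- win * sin(2 * pi * freqs[j] * t_idx / sample_rate)
  }
  if (d %% 2 == 1) W[, d] <- win / sqrt(stride)
  W + matrix(stats::rnorm(stride * d, sd = 1e-3), stride, d)
}

#' Select the encoder output layer
#'
#' Frame embeddings are then read after block `layer`; blocks above it are
#' never executed, so the output is independent of their parameters.
#'
#' @param encoder A `tiny_encoder`.
#' @param layer Block index in `[1, n_layers]`.
#' @return The modified encoder.
#' @export
set_encoder_layer <- function(encoder, layer) {
  if (layer < 1 || layer > encoder$n_layers)
    stopf("layer must lie in [1, %d]", encoder$n_layers)
  encoder$layer <- as.integer(layer)
  encoder
}

# Forward pass over a batch: waves is a B x L matrix (rows are clips of
# equal length). Returns pooled embeddings plus per-clip caches for the
# backward pass.
encoder_forward <- function(encoder, waves, want_cache = FALSE) {
  stopifnot(is.matrix(waves))
  stride <- encoder$stride
  n_frames <- ncol(waves) %/% stride
  if (n_frames < 1) stopf("input shorter than one encoder frame")
  layer <- encoder$layer
  B <- nrow(waves)
  caches <- if (want_cache) vector("list", B) else NULL
  emb <- matrix(0, B, encoder$d)
  frames_out <- vector("list", B)
  for (b in seq_len(B)) {
    fr <- matrix(waves[b, seq_len(n_frames * stride)], nrow = stride)
    fr <- t(fr)                                    # T x stride
    lin <- linear_fwd(fr, encoder$params$conv$W, encoder$params$conv$b)
    rl <- relu_fwd(lin$out)
    g <- encoder$comp_gain %||% 0
    x <- if (g > 0) log1p(g * rl$out) else rl$out
    blk_caches <- vector("list", layer)
    prenorm <- encoder$prenorm_attention %||% TRUE
    for (l in seq_len(layer)) {
      bc <- block_fwd(x, encoder$params$blocks[[l]], prenorm = prenorm)
      x <- bc$out
      blk_caches[[l]] <- bc
    }
    emb[b, ] <- colMeans(x)
    frames_out[[b]] <- x
    if (want_cache) caches[[b]] <- list(lin = lin, rl = rl,
                                        blocks = blk_caches)
  }
  list(emb = emb, frames = frames_out, caches = caches,
       n_frames = n_frames, layer = layer)
}

# Backward from d(pooled embedding) to encoder parameter gradients.
# Returns the gradient tree plus, per clip, the gradient at the final used
# block's attention output projection (the Grad-CAM hook).
encoder_backward <- function(encoder, fwd, demb) {
  grads <- tree_zeros_like(encoder$params)
  layer <- fwd$layer
  Tn <- fwd$n_frames
  hook_do <- vector("list", nrow(demb))
  for (b in seq_len(nrow(demb))) {
    cache <- fwd$caches[[b]]
    dx <- matrix(rep(demb[b, ] / Tn, each = Tn), nrow = Tn)
    for (l in rev(seq_len(layer))) {
      bb <- block_bwd(cache$blocks[[l]], encoder$params$blocks[[l]], dx)
      dx <- bb$dx
      grads$blocks[[l]] <- tree_add(grads$blocks[[l]], bb$grads)
      if (l == layer) hook_do[[b]] <- bb$do
    }
    g <- encoder$comp_gain %||% 0
    if (g > 0) dx <- dx * g / (1 + g * cache$rl$out)
    drl <- relu_bwd(cache$rl, dx)
    lb <- linear_bwd(cache$lin, encoder$params$conv$W, drl)
    grads$conv$W <- grads$conv$W + lb$dW
    grads$conv$b <- grads$conv$b + lb$db
  }
  list(grads = grads, hook_do = hook_do)
}

#' Mean-pool a frame-embedding matrix to an utterance embedding
#'
#' @param frames A `T x d` numeric matrix of frame embeddings.
#' @return Length-`d` numeric vector (the arithmetic mean over time).
#' @export
pool_frames <- function(frames) {
  if (!is.matrix(frames) || nrow(frames) < 1)
    stopf("frames must be a non-empty T x d matrix")
  colMeans(frames)
}

# ---- dual heads -------------------------------------------------------------

init_classifier <- function(d, hidden = 64, n_classes = 2) {
  list(W1 = nn_init_mat(d, hidden), b1 = rep(0, hidden),
       W2 = nn_init_mat(hidden, n_classes), b2 = rep(0, n_classes))
}

init_projector <- function(d, hidden = 128, p = 32) {
  list(W1 = nn_init_mat(d, hidden), b1 = rep(0, hidden),
       W2 = nn_init_mat(hidden, p), b2 = rep(0, p))
}

#' Assemble the dual-head model
#'
#' Pairs a frame-level encoder with the two heads of the single-phase
#' contrastive fine-tuning scheme: a classification head (linear to 64
#' units, ReLU, dropout 0.2, linear to 2 logits) and a projection head
#' (two-layer perceptron to a `p`-dimensional L2-normalized vector on which
#' the supervised contrastive loss operates).
#'
#' @param encoder An encoder from [make_tiny_encoder()] (or any object with
#'   the same contract).
#' @param p Projection output width (the "projection head size"; default 32).
#' @param proj_hidden Projection hidden width (default 128).
#' @param clf_hidden Classifier hidden width (default 64).
#' @param dropout Classifier dropout rate (default 0.2, train mode only).
#' @param seed Integer seed for head initialization.
#' @return An object of class `supcon_model`.
#' @export
supcon_model <- function(encoder, p = 32, proj_hidden = 128, clf_hidden = 64,
                         dropout = 0.2, seed = 1) {
  if (p < 2) stopf("projection width p must be >= 2")
  heads <- with_seed(combine_seed(seed, "heads"), {
    list(classifier = init_classifier(encoder$d, clf_hidden),
         projector = init_projector(encoder$d, proj_hidden, p))
  })
  structure(list(encoder = encoder, classifier = heads$classifier,
                 projector = heads$projector, p = as.integer(p),
                 dropout = dropout),
            class = "supcon_model")
}

#' Classification head forward pass
#'
#' Linear `d -> 64`, ReLU, dropout (training mode only), linear `64 -> 2`.
#' Evaluation mode is deterministic.
#'
#' @param model A [supcon_model()].
#' @param emb `B x d` embedding matrix (or length-`d` vector).
#' @param train_mode Logical; enables dropout.
#' @param seed Optional integer seed for the dropout mask.
#' @return `B x 2` logit matrix.
#' @export
classifier_forward <- function(model, emb, train_mode = FALSE, seed = NULL) {
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1)
  if (ncol(emb) != model$encoder$d)
    stopf("embedding width %d does not match encoder d=%d",
          ncol(emb), model$encoder$d)
  run <- function() classifier_fwd_cached(model$classifier, emb,
                                          model$dropout, train_mode)$out
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

classifier_fwd_cached <- function(clf, emb, dropout, train_mode) {
  l1 <- linear_fwd(emb, clf$W1, clf$b1)
  r1 <- relu_fwd(l1$out)
  dp <- dropout_fwd(r1$out, dropout, train_mode)
  l2 <- linear_fwd(dp$out, clf$W2, clf$b2)
  list(out = l2$out, l1 = l1, r1 = r1, dp = dp, l2 = l2)
}

classifier_bwd <- function(clf, cache, dlogits) {
  b2 <- linear_bwd(cache$l2, clf$W2, dlogits)
  ddp <- dropout_bwd(cache$dp, b2$dx)
  dr1 <- relu_bwd(cache$r1, ddp)
  b1 <- linear_bwd(cache$l1, clf$W1, dr1)
  list(demb = b1$dx,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

#' Projection head forward pass
#'
#' Two-layer perceptron `d -> h -> p` followed by L2 normalization onto the
#' unit hypersphere. An epsilon guard keeps the normalization finite for a
#' zero pre-normalization vector.
#'
#' @inheritParams classifier_forward
#' @return `B x p` matrix of unit-norm projections.
#' @export
projector_forward <- function(model, emb) {
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1)
  projector_fwd_cached(model$projector, emb)$z
}

projector_fwd_cached <- function(proj, emb, eps = 1e-12) {
  l1 <- linear_fwd(emb, proj$W1, proj$b1)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, proj$W2, proj$b2)
  u <- l2$out
  norms <- sqrt(rowSums(u^2))
  z <- u / pmax(norms, eps)
  list(z = z, u = u, norms = pmax(norms, eps), l1 = l1, r1 = r1, l2 = l2)
}

projector_bwd <- function(proj, cache, dz) {
  z <- cache$z
  du <- (dz - z * rowSums(dz * z)) / cache$norms
  b2 <- linear_bwd(cache$l2, proj$W2, du)
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- linear_bwd(cache$l1, proj$W1, dr1)
  list(demb = b1$dx,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

#' Dual-pathway forward pass
#'
#' In `SUPCON` mode the projection head reads the live utterance embedding
#' while the classification head reads a gradient-detached copy of the same
#' values, so classification loss can never update the encoder. In
#' `CE_ONLY` mode (plain fine-tuning) the classifier reads the live
#' embedding and the projection path is omitted.
#'
#' @param model A [supcon_model()].
#' @param waves `B x L` waveform matrix of standardized clips.
#' @param mode `"SUPCON"` or `"CE_ONLY"`.
#' @param train_mode Logical; enables classifier dropout.
#' @param seed Optional seed for the dropout mask.
#' @return List with `logits` (`B x 2`), `z` (`B x p`, `SUPCON` only),
#'   `emb`, and forward caches for [dual_backward()].
#' @export
dual_forward <- function(model, waves, mode = c("SUPCON", "CE_ONLY"),
                         train_mode = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  enc <- encoder_forward(model$encoder, waves, want_cache = TRUE)
  run_clf <- function() classifier_fwd_cached(model$classifier, enc$emb,
                                              model$dropout, train_mode)
  clf <- if (!is.null(seed)) with_seed(combine_seed(seed, "dropout"), run_clf())
         else run_clf()
  prj <- if (mode == "SUPCON") projector_fwd_cached(model$projector, enc$emb)
         else NULL
  list(logits = clf$out, z = if (!is.null(prj)) prj$z else NULL,
       emb = enc$emb, enc = enc, clf = clf, prj = prj, mode = mode)
}

#' Dual-pathway backward pass with gradient blocking
#'
#' Accumulates parameter gradients from the supplied output gradients. In
#' `SUPCON` mode the classifier pathway is detached: `dlogits` updates only
#' the classification head, and only `dz` (through the projection head)
#' reaches the encoder. In `CE_ONLY` mode `dlogits` flows through to the
#' encoder. With `fine_tune_encoder = FALSE` the encoder gradient is zero
#' regardless.
#'
#' @param model A [supcon_model()].
#' @param fwd The cache list returned by [dual_forward()].
#' @param dlogits Gradient of the loss w.r.t. the logits (`B x 2`), or NULL.
#' @param dz Gradient w.r.t. the projections (`B x p`), or NULL
#'   (`SUPCON` mode only).
#' @param fine_tune_encoder Logical; if FALSE the encoder is frozen.
#' @return List of gradient trees `encoder`, `classifier`, `projector`
#'   (exact zeros where a pathway is blocked).
#' @export
dual_backward <- function(model, fwd, dlogits = NULL, dz = NULL,
                          fine_tune_encoder = TRUE) {
  g_enc <- tree_zeros_like(model$encoder$params)
  g_clf <- tree_zeros_like(model$classifier)
  g_prj <- tree_zeros_like(model$projector)
  demb <- matrix(0, nrow(fwd$emb), ncol(fwd$emb))
  touched <- FALSE
  if (!is.null(dlogits)) {
    cb <- classifier_bwd(model$classifier, fwd$clf, dlogits)
    g_clf <- tree_add(g_clf, cb$grads)
    if (fwd$mode == "CE_ONLY") {           # live pathway: gradient reaches encoder
      demb <- demb + cb$demb
      touched <- TRUE
    }                                      # SUPCON: detached copy, blocked here
  }
  if (!is.null(dz)) {
    if (fwd$mode != "SUPCON") stopf("dz is only defined in SUPCON mode")
    pb <- projector_bwd(model$projector, fwd$prj, dz)
    g_prj <- tree_add(g_prj, pb$grads)
    demb <- demb + pb$demb
    touched <- TRUE
  }
  hook <- NULL
  if (touched && fine_tune_encoder) {
    eb <- encoder_backward(model$encoder, fwd$enc, demb)
    g_enc <- eb$grads
    hook <- eb$hook_do
  }
  list(encoder = g_enc, classifier = g_clf, projector = g_prj,
       hook_do = hook)
}
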