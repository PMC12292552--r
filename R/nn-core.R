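# Minimal dense neural-network toolkit with explicit forward caches and
# hand-derived backward passes. Parameters and gradients are nested named
# lists of matrices/vectors with identical shapes; AdamW walks the
# flattened tree. Everything is plain double-precision BLAS matrix algebra,
# so runs are bit-reproducible for a fixed seed on one platform.

nn_init_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# ---- tree utilities ---------------------------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

tree_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, tree_zeros_like)
  else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_add <- function(a, b) tree_map2(a, b, `+`)

tree_all_zero <- function(p) {
  all(vapply(flatten_params(p), function(x) all(x == 0), logical(1)))
}

tree_max_abs <- function(p) {
  max(vapply(flatten_params(p), function(x) max(abs(x)), numeric(1)))
}

tree_identical <- function(a, b) {
  fa <- flatten_params(a); fb <- flatten_params(b)
  identical(lapply(fa, as.numeric), lapply(fb, as.numeric))
}

# ---- primitive layers -------------------------------------------------------

linear_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, x = x)
}
linear_bwd <- function(cache, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dout) dout * cache$mask

# Inverted dropout; mask drawn from the current RNG stream.
dropout_fwd <- function(x, rate, train_mode) {
  if (!train_mode || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}
dropout_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  n <- nrow(x)
  out <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = out, xhat = xhat, inv = inv)
}
layernorm_bwd <- function(cache, g, dout) {
  xhat <- cache$xhat
  dxhat <- dout * rep(g, each = nrow(dout))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

softmax_rows <- function(s) {
  rmax <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - rmax)
  e / rowSums(e)
}

# Single-head scaled-dot-product self-attention over a T x d sequence,
# with output projection Wo (the Grad-CAM hook tensor is `o`).
attn_fwd <- function(x, p) {
  d <- ncol(x)
  q <- x %*% p$Wq; k <- x %*% p$Wk; v <- x %*% p$Wv
  s <- tcrossprod(q, k) / sqrt(d)
  a <- softmax_rows(s)
  ctx <- a %*% v
  o <- ctx %*% p$Wo
  o <- o + rep(p$bo, each = nrow(o))
  list(out = o, x = x, q = q, k = k, v = v, a = a, ctx = ctx)
}
attn_bwd <- function(cache, p, dout) {
  d <- ncol(cache$x)
  dWo <- crossprod(cache$ctx, dout)
  dbo <- colSums(dout)
  dctx <- dout %*% t(p$Wo)
  da <- tcrossprod(dctx, cache$v)
  dv <- crossprod(cache$a, dctx)
  ds <- cache$a * (da - rowSums(da * cache$a))
  dq <- (ds %*% cache$k) / sqrt(d)
  dk <- (crossprod(ds, cache$q)) / sqrt(d)
  dx <- dq %*% t(p$Wq) + dk %*% t(p$Wk) + dv %*% t(p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(cache$x, dq), Wk = crossprod(cache$x, dk),
                    Wv = crossprod(cache$x, dv), Wo = dWo, bo = dbo))
}

# Pre-norm transformer block: attention + residual, then feed-forward +
# residual. `o` (attention output-projection activation) is cached for
# Grad-CAM.
block_fwd <- function(x, p, prenorm = TRUE) {
  ln1 <- if (prenorm) layernorm_fwd(x, p$ln1$g, p$ln1$b) else list(out = x)
  att <- attn_fwd(ln1$out, p$attn)
  x1 <- x + att$out
  ln2 <- layernorm_fwd(x1, p$ln2$g, p$ln2$b)
  l1 <- linear_fwd(ln2$out, p$ffn$W1, p$ffn$b1)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, p$ffn$W2, p$ffn$b2)
  list(out = x1 + l2$out, ln1 = ln1, att = att, x1 = x1, ln2 = ln2,
       l1 = l1, r1 = r1, l2 = l2, prenorm = prenorm)
}
# Returns dx, parameter grads, and the gradient at the attention output
# projection (`do`) for Grad-CAM.
block_bwd <- function(cache, p, dout) {
  b2 <- linear_bwd(cache$l2, p$ffn$W2, dout)
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- linear_bwd(cache$l1, p$ffn$W1, dr1)
  ln2 <- layernorm_bwd(cache$ln2, p$ln2$g, b1$dx)
  dx1 <- dout + ln2$dx
  do <- dx1
  ab <- attn_bwd(cache$att, p$attn, do)
  if (isTRUE(cache$prenorm)) {
    ln1 <- layernorm_bwd(cache$ln1, p$ln1$g, ab$dx)
    dx <- dx1 + ln1$dx
    g_ln1 <- list(g = ln1$dg, b = ln1$db)
  } else {
    dx <- dx1 + ab$dx
    g_ln1 <- list(g = p$ln1$g * 0, b = p$ln1$b * 0)
  }
  list(dx = dx, do = do,
       grads = list(ln1 = g_ln1, attn = ab$grads,
                    ln2 = list(g = ln2$dg, b = ln2$db),
                    ffn = list(W1 = b1$dW, b1 = b1$db,
                               W2 = b2$dW, b2 = b2$db)))
}

init_block_params <- function(d, ffn_mult = 2) {
  h <- d * ffn_mult
  list(ln1 = list(g = rep(1, d), b = rep(0, d)),
       attn = list(Wq = nn_init_mat(d, d), Wk = nn_init_mat(d, d),
                   Wv = nn_init_mat(d, d), Wo = nn_init_mat(d, d) * 0.5,
                   bo = rep(0, d)),
       ln2 = list(g = rep(1, d), b = rep(0, d)),
       ffn = list(W1 = nn_init_mat(d, h), b1 = rep(0, h),
                  W2 = nn_init_mat(h, d) * 0.5, b2 = rep(0, d)))
}

# ---- softmax cross-entropy --------------------------------------------------

# Mean negative log-likelihood over the batch; labels are 1-based class ids.
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  probs <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

# ---- AdamW optimizer --------------------------------------------------------

adamw_state <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

# Decoupled weight decay; lr supplied per call (scheduler lives outside).
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(fp)) {
    g <- fg[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / bc1
    vhat <- state$v[[key]] / bc2
    decay <- if (grepl("(^|\\.)b[o12]?$|ln[12]", key)) 0 else weight_decay
    fp[[key]] <- fp[[key]] - lr * (mhat / (sqrt(vhat) + eps) + decay * fp[[key]])
  }
  list(params = unflatten_params(fp, params), state = state)
}

unflatten_params <- function(flat, template, prefix = "") {
  out <- template
  for (nm in names(template)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(template[[nm]]))
      out[[nm]] <- unflatten_params(flat, template[[nm]], key)
    else {
      v <- flat[[key]]
      if (is.null(dim(template[[nm]]))) out[[nm]] <- as.numeric(v)
      else out[[nm]] <- matrix(v, nrow(template[[nm]]))
    }
  }
  out
}

cosine_lr <- function(initial_lr, epoch, total_epochs, floor_frac = 0.05) {
  frac <- (epoch - 1) / max(1, total_epochs)
  initial_lr * (floor_frac + (1 - floor_frac) * 0.5 * (1 + cos(pi * frac)))
}
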