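# Small encoders (short stride, small d) keep these structural tests fast;
# the stride-320 contract itself is checked explicitly.

test_that("frame count follows the stride contract (80,000 samples -> 250)", {
  enc <- make_tiny_encoder(d = 8, n_layers = 1, seed = 1)
  fwd <- supconvoice:::encoder_forward(enc, matrix(0.01, 1, 80000))
  expect_equal(fwd$n_frames, 250)
  expect_equal(dim(fwd$frames[[1]]), c(250, 8))
})

test_that("encoder initialization is deterministic in the seed", {
  a <- make_tiny_encoder(16, 2, seed = 9, stride = 32L)
  b <- make_tiny_encoder(16, 2, seed = 9, stride = 32L)
  c <- make_tiny_encoder(16, 2, seed = 10, stride = 32L)
  expect_true(supconvoice:::tree_identical(a$params, b$params))
  expect_false(supconvoice:::tree_identical(a$params, c$params))
  expect_error(make_tiny_encoder(d = 4), ">= 8")
  expect_error(make_tiny_encoder(n_layers = 0), ">= 1")
})

test_that("layer selection returns the intermediate activation and ignores later blocks", {
  set.seed(3)
  enc <- make_tiny_encoder(16, 3, seed = 2, stride = 32L)
  waves <- matrix(rnorm(2 * 640, sd = 0.2), 2)
  full <- supconvoice:::encoder_forward(enc, waves)
  enc1 <- set_encoder_layer(enc, 1)
  out1 <- supconvoice:::encoder_forward(enc1, waves)
  # manual recomputation of block 1 output from the front end
  manual <- local({
    fr <- t(matrix(waves[1, ], nrow = 32))
    lin <- supconvoice:::linear_fwd(fr, enc$params$conv$W, enc$params$conv$b)
    x <- log1p(enc$comp_gain * pmax(lin$out, 0))
    supconvoice:::block_fwd(x, enc$params$blocks[[1]],
                            prenorm = enc$prenorm_attention)$out
  })
  expect_equal(out1$frames[[1]], manual, tolerance = 1e-12)
  # perturbing block 3 parameters cannot change layer-2 output
  enc_pert <- set_encoder_layer(enc, 2)
  base <- supconvoice:::encoder_forward(enc_pert, waves)
  enc_pert$params$blocks[[3]]$attn$Wq <- enc_pert$params$blocks[[3]]$attn$Wq + 10
  after <- supconvoice:::encoder_forward(enc_pert, waves)
  expect_identical(base$emb, after$emb)
  expect_error(set_encoder_layer(enc, 4), "\\[1, 3\\]")
})

test_that("pool_frames is the column mean with permutation invariance", {
  v <- c(1.5, -2, 0.25, 4)
  same <- matrix(rep(v, each = 6), 6)
  expect_equal(pool_frames(same), v)
  set.seed(8)
  m <- matrix(rnorm(28), 7, 4)
  manual <- vapply(1:4, function(j) sum(m[, j]) / 7, numeric(1))
  expect_equal(pool_frames(m), manual, tolerance = 1e-12)
  expect_equal(pool_frames(m[sample(7), ]), pool_frames(m), tolerance = 1e-12)
  expect_error(pool_frames(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("classifier head has a 64-unit hidden layer and deterministic eval mode", {
  enc <- make_tiny_encoder(16, 1, seed = 1, stride = 32L)
  model <- supcon_model(enc, seed = 2)
  expect_equal(dim(model$classifier$W1), c(16, 64))
  expect_equal(dim(model$classifier$W2), c(64, 2))
  emb <- matrix(rnorm(3 * 16), 3)
  l1 <- classifier_forward(model, emb, train_mode = FALSE)
  l2 <- classifier_forward(model, emb, train_mode = FALSE)
  expect_identical(l1, l2)
  expect_equal(dim(l1), c(3, 2))
  # zero weights and biases produce zero logits for any input
  zero_model <- model
  zero_model$classifier <- lapply(model$classifier, function(x) x * 0)
  expect_equal(classifier_forward(zero_model, emb),
               matrix(0, 3, 2))
  expect_error(classifier_forward(model, matrix(0, 2, 5)), "width")
})

test_that("projection head outputs unit-norm vectors of the configured width", {
  enc <- make_tiny_encoder(16, 1, seed = 1, stride = 32L)
  model <- supcon_model(enc, p = 32, seed = 3)
  emb <- matrix(rnorm(5 * 16), 5)
  z <- projector_forward(model, emb)
  expect_equal(dim(z), c(5, 32))
  expect_equal(sqrt(rowSums(z^2)), rep(1, 5), tolerance = 1e-6)
  # zero embedding: epsilon-guarded, never NaN
  z0 <- projector_forward(model, matrix(0, 1, 16))
  expect_true(all(is.finite(z0)))
})

test_that("projection is scale-invariant through a bias-free ReLU pipeline", {
  enc <- make_tiny_encoder(16, 1, seed = 1, stride = 32L)
  model <- supcon_model(enc, p = 8, seed = 4)
  model$projector$b1 <- model$projector$b1 * 0
  model$projector$b2 <- model$projector$b2 * 0
  emb <- matrix(abs(rnorm(2 * 16)), 2)
  expect_equal(projector_forward(model, emb * 10),
               projector_forward(model, emb), tolerance = 1e-6)
})

test_that("dual_forward honours the batch shape contract in both modes", {
  enc <- make_tiny_encoder(16, 2, seed = 5, stride = 32L)
  model <- supcon_model(enc, p = 12, seed = 5)
  waves <- matrix(rnorm(4 * 320, sd = 0.2), 4)
  sup <- dual_forward(model, waves, mode = "SUPCON")
  expect_equal(dim(sup$logits), c(4, 2))
  expect_equal(dim(sup$z), c(4, 12))
  expect_equal(sqrt(rowSums(sup$z^2)), rep(1, 4), tolerance = 1e-6)
  ce <- dual_forward(model, waves, mode = "CE_ONLY")
  expect_null(ce$z)
  expect_error(dual_forward(model, waves, mode = "BOTH"))
})

test_that("gradient blocking severs exactly the specified pathways", {
  enc <- make_tiny_encoder(16, 2, seed = 6, stride = 32L)
  model <- supcon_model(enc, p = 8, seed = 6)
  waves <- matrix(rnorm(4 * 320, sd = 0.2), 4)
  labels <- c("HC", "HC", "PD", "PD")
  fwd <- dual_forward(model, waves, mode = "SUPCON")
  ce <- supconvoice:::softmax_ce(fwd$logits, supconvoice:::label_ids(labels))

  # classification loss alone: encoder and projector untouched, exactly
  g_ce <- dual_backward(model, fwd, dlogits = ce$dlogits)
  expect_true(supconvoice:::tree_all_zero(g_ce$encoder))
  expect_true(supconvoice:::tree_all_zero(g_ce$projector))
  expect_false(supconvoice:::tree_all_zero(g_ce$classifier))

  # contrastive loss alone: classifier head untouched, exactly
  sc <- supcon_loss(fwd$z, labels, supcon_config(temperature = 0.5),
                    want_grad = TRUE)
  g_sc <- dual_backward(model, fwd, dz = attr(sc, "dz"))
  expect_true(supconvoice:::tree_all_zero(g_sc$classifier))
  expect_false(supconvoice:::tree_all_zero(g_sc$encoder))
  expect_false(supconvoice:::tree_all_zero(g_sc$projector))

  # CE_ONLY mode: classification loss reaches the encoder
  fwd2 <- dual_forward(model, waves, mode = "CE_ONLY")
  ce2 <- supconvoice:::softmax_ce(fwd2$logits, supconvoice:::label_ids(labels))
  g2 <- dual_backward(model, fwd2, dlogits = ce2$dlogits)
  expect_false(supconvoice:::tree_all_zero(g2$encoder))

  # frozen encoder: zero encoder gradient even on the live pathway
  g3 <- dual_backward(model, fwd2, dlogits = ce2$dlogits,
                      fine_tune_encoder = FALSE)
  expect_true(supconvoice:::tree_all_zero(g3$encoder))
})

test_that("analytic gradients match finite differences on every pathway", {
  sv <- asNamespace("supconvoice")
  set.seed(42)
  enc <- make_tiny_encoder(d = 8, n_layers = 2, seed = 3, stride = 16L)
  model <- supcon_model(enc, p = 4, proj_hidden = 8, clf_hidden = 6,
                        dropout = 0, seed = 5)
  waves <- matrix(rnorm(3 * 64, sd = 0.3), 3, 64)
  labels <- c("HC", "PD", "PD")
  sup_only <- function(m) {
    fwd <- dual_forward(m, waves, mode = "SUPCON")
    as.numeric(hard_negative_adjust(fwd$z, labels,
                                    supcon_config(temperature = 0.5)))
  }
  ce_live <- function(m) {
    fwd <- dual_forward(m, waves, mode = "CE_ONLY")
    sv$softmax_ce(fwd$logits, sv$label_ids(labels))$loss
  }
  fwd <- dual_forward(model, waves, mode = "SUPCON")
  sc <- hard_negative_adjust(fwd$z, labels, supcon_config(temperature = 0.5),
                             want_grad = TRUE)
  g_sup <- dual_backward(model, fwd, dz = attr(sc, "dz"))
  fwd2 <- dual_forward(model, waves, mode = "CE_ONLY")
  ce2 <- sv$softmax_ce(fwd2$logits, sv$label_ids(labels))
  g_ce <- dual_backward(model, fwd2, dlogits = ce2$dlogits)

  num_grad_check <- function(comp, grads, loss_fn) {
    p_tree <- if (comp == "encoder") model$encoder$params else model[[comp]]
    fp <- sv$flatten_params(p_tree)
    fg <- sv$flatten_params(grads[[comp]])
    eps <- 1e-6
    worst <- 0
    for (key in names(fp)) {
      for (j in sample(length(fp[[key]]), min(2, length(fp[[key]])))) {
        m2 <- model
        tp <- fp
        tp[[key]][j] <- fp[[key]][j] + eps
        nt <- sv$unflatten_params(tp, p_tree)
        if (comp == "encoder") m2$encoder$params <- nt else m2[[comp]] <- nt
        lp <- loss_fn(m2)
        tp[[key]][j] <- fp[[key]][j] - eps
        nt <- sv$unflatten_params(tp, p_tree)
        if (comp == "encoder") m2$encoder$params <- nt else m2[[comp]] <- nt
        lm <- loss_fn(m2)
        num <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(num - fg[[key]][j]) / max(1, abs(num)))
      }
    }
    worst
  }
  expect_lt(num_grad_check("encoder", g_sup, sup_only), 1e-5)
  expect_lt(num_grad_check("projector", g_sup, sup_only), 1e-5)
  expect_lt(num_grad_check("encoder", g_ce, ce_live), 1e-5)
  expect_lt(num_grad_check("classifier", g_ce, ce_live), 1e-5)
})
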