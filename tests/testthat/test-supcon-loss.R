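test_that("loss vanishes for a two-sample same-class batch", {
  for (seed in 1:5) {
    b <- random_projection_batch(2, 3, seed)
    b$labels <- c("PD", "PD")
    for (tau in c(0.07, 0.5, 3))
      expect_equal(supcon_loss(b$z, b$labels,
                               supcon_config(temperature = tau)), 0)
  }
})

test_that("large-temperature limit approaches N log(N - 1)", {
  b <- random_projection_batch(4, 3, 11)
  labels <- c("HC", "HC", "PD", "PD")
  l_inf <- supcon_loss(b$z, labels, supcon_config(temperature = 1e6))
  expect_equal(l_inf, 4 * log(3), tolerance = 1e-3)
  # the gap to the limit shrinks monotonically in temperature
  gaps <- vapply(c(10, 100, 1e6), function(tau)
    abs(supcon_loss(b$z, labels, supcon_config(temperature = tau)) -
          4 * log(3)), numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("vectorized loss matches the naive double-loop oracle", {
  worst_plain <- 0
  worst_hard <- 0
  for (seed in 1:60) {
    n <- sample(2:8, 1)
    b <- random_projection_batch(n, sample(2:4, 1), seed + 500)
    tau <- runif(1, 0.05, 2)
    k <- sample(0:3, 1)
    worst_plain <- max(worst_plain, abs(
      supcon_loss(b$z, b$labels, supcon_config(temperature = tau)) -
        naive_supcon(b$z, b$labels, tau)))
    worst_hard <- max(worst_hard, abs(
      hard_negative_adjust(b$z, b$labels,
                           supcon_config(temperature = tau,
                                         hard_scale = 1.5, hard_k = k)) -
        naive_supcon(b$z, b$labels, tau, 1.5, k)))
  }
  expect_lt(worst_plain, 1e-6)
  expect_lt(worst_hard, 1e-6)
})

test_that("hard scaling reduces to the plain loss at scale 1 and strictly exceeds it otherwise", {
  for (seed in 1:20) {
    b <- random_projection_batch(6, 3, seed + 90)
    if (length(unique(b$labels)) < 2) b$labels <- c("HC", b$labels[-1])
    plain <- supcon_loss(b$z, b$labels, supcon_config())
    at_one <- hard_negative_adjust(b$z, b$labels,
                                   supcon_config(hard_scale = 1))
    expect_identical(as.numeric(at_one), as.numeric(plain))
    disabled <- hard_negative_adjust(b$z, b$labels,
                                     supcon_config(hard_enabled = FALSE))
    expect_identical(as.numeric(disabled), as.numeric(plain))
    scaled <- hard_negative_adjust(b$z, b$labels,
                                   supcon_config(hard_scale = 1.5))
    has_pos_and_neg <- any(table(b$labels) >= 2) &&
      length(unique(b$labels)) == 2
    if (has_pos_and_neg) expect_gt(scaled, plain)
  }
})

test_that("both losses are invariant under batch permutation", {
  b <- random_projection_batch(7, 4, 33)
  perm <- sample(7)
  for (fn in list(supcon_loss, hard_negative_adjust)) {
    l1 <- fn(b$z, b$labels, supcon_config())
    l2 <- fn(b$z[perm, ], b$labels[perm], supcon_config())
    expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-9)
  }
})

test_that("loss stays finite at low temperature with near-duplicate rows", {
  z <- matrix(c(1, 0, 1, 1e-9, -1, 1e-9, 1, -1e-9), 4, 2, byrow = TRUE)
  z <- z / sqrt(rowSums(z^2))
  labels <- c("PD", "PD", "HC", "HC")
  l <- supcon_loss(z, labels, supcon_config(temperature = 0.01))
  expect_true(is.finite(l))
  lh <- hard_negative_adjust(z, labels, supcon_config(temperature = 0.01))
  expect_true(is.finite(lh))
})

test_that("a gradient step decreases the loss on clustered projections", {
  passes <- 0
  for (seed in 1:20) {
    set.seed(seed)
    centers <- matrix(rnorm(2 * 4), 2)
    z <- rbind(centers[rep(1, 4), ] + matrix(rnorm(16, sd = 0.6), 4),
               centers[rep(2, 4), ] + matrix(rnorm(16, sd = 0.6), 4))
    z <- z / sqrt(rowSums(z^2))
    labels <- rep(c("HC", "PD"), each = 4)
    cfg <- supcon_config(temperature = 0.3)
    l0 <- hard_negative_adjust(z, labels, cfg, want_grad = TRUE)
    step_ok <- FALSE
    for (lr in c(0.1, 0.03, 0.01)) {          # line search
      z1 <- z - lr * attr(l0, "dz")
      z1 <- z1 / sqrt(rowSums(z1^2))
      if (hard_negative_adjust(z1, labels, cfg) < as.numeric(l0)) {
        step_ok <- TRUE
        break
      }
    }
    passes <- passes + step_ok
  }
  expect_equal(passes, 20)
})

test_that("invalid projection batches are rejected", {
  b <- random_projection_batch(4, 3, 2)
  expect_error(supcon_loss(b$z[1, , drop = FALSE], b$labels[1]), "N >= 2")
  bad <- b$z * 2
  expect_error(supcon_loss(bad, b$labels), "unit-norm")
  expect_error(supcon_config(temperature = 0), "positive")
  expect_error(supcon_config(hard_scale = 0.5), ">= 1")
})

test_that("combined objective is the exact sum of its reported components", {
  b <- random_projection_batch(6, 4, 77)
  set.seed(78)
  logits <- matrix(rnorm(12), 6)
  res <- combined_objective(logits, b$z, b$labels, supcon_config())
  expect_equal(res$total, res$supcon + res$cross_entropy, tolerance = 1e-9)
  expect_equal(res$supcon,
               as.numeric(hard_negative_adjust(b$z, b$labels,
                                               supcon_config())),
               tolerance = 1e-12)

  # all-zero logits: cross-entropy is log 2 per sample
  res0 <- combined_objective(matrix(0, 6, 2), b$z, b$labels, supcon_config())
  expect_equal(res0$cross_entropy, log(2), tolerance = 1e-12)

  # two same-class samples: contrastive component vanishes, total = CE
  z2 <- random_projection_batch(2, 3, 5)$z
  res2 <- combined_objective(matrix(c(1, -1, 0.5, 2), 2), z2, c("PD", "PD"),
                             supcon_config())
  expect_equal(res2$supcon, 0)
  expect_equal(res2$total, res2$cross_entropy)

  expect_error(combined_objective(logits[1:3, ], b$z, b$labels), "mismatch")
})
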