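test_that("encoder configuration validates architecture invariants", {
  expect_error(encoder_config(1280, kernels = c(8L, 16L, 32L)), "decreasing")
  expect_error(encoder_config(1280, filters = c(32L, 64L)), "equal length")
  expect_error(encoder_config(16L), "block 1")
  sh <- encoder_shapes(encoder_config(2560))
  expect_identical(unname(sh$layers$conv1), c(32L, 1L, 32L))
  expect_identical(unname(sh$layers$conv2), c(16L, 32L, 64L))
  expect_identical(unname(sh$layers$conv3), c(8L, 64L, 128L))
  expect_equal(sh$h_dim, sh$final_length * 80L)
})

test_that("weight initialization is deterministic and shape-consistent", {
  cfg <- tiny_encoder_cfg()
  w1 <- build_encoder(cfg, seed = 11)
  w2 <- build_encoder(cfg, seed = 11)
  expect_identical(w1$params, w2$params)
  w3 <- build_encoder(cfg, seed = 12)
  expect_false(identical(w1$params, w3$params))
  expect_equal(dim(w1$params$conv1_W), c(16L * 1L, 4L))
  expect_equal(dim(w1$params$conv2_W), c(8L * 4L, 6L))
  expect_equal(dim(w1$params$dense_W), c(8L, 8L))
})

test_that("encoder forward pass is deterministic in eval mode and linear at zero", {
  cfg <- tiny_encoder_cfg()
  w <- build_encoder(cfg, seed = 1)
  x <- matrix(stats::rnorm(5 * 128), 5, 128)
  h1 <- encoder_forward(w, x)
  h2 <- encoder_forward(w, x)
  expect_identical(h1, h2)
  expect_equal(ncol(h1), encoder_shapes(cfg)$h_dim)

  h0 <- encoder_forward(w, matrix(0, 3, 128))
  expect_true(all(h0 == 0))  # zero biases + ReLU(0) = 0

  expect_error(encoder_forward(w, matrix(0, 2, 64)), "does not match")
})

test_that("projection head rows are simplex points with preserved ranking", {
  cfg <- tiny_encoder_cfg()
  pw <- build_projection(projection_config(units = 16L), encoder_shapes(cfg)$h_dim,
                         seed = 2)
  h <- matrix(stats::rnorm(6 * encoder_shapes(cfg)$h_dim), 6)
  z <- projection_forward(pw, h)
  expect_equal(rowSums(z), rep(1, 6), tolerance = 1e-6)
  expect_true(all(z > 0 & z < 1))
  u <- h %*% pw$params$proj_W + rep(pw$params$proj_b, each = 6)
  expect_identical(apply(u, 1, order), apply(z, 1, order))  # softmax monotone
})

test_that("cosine similarity matches its closed forms", {
  expect_equal(cosine_sim(c(3, 4), c(3, 4)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero vectors")
})

test_that("NT-Xent equals the brute-force oracle and respects its symmetries", {
  withr::local_seed(8)
  for (rep in 1:30) {
    N <- sample(1:8, 1)
    d <- sample(c(4L, 16L), 1)
    tau <- sample(c(0.1, 0.5, 1.0), 1)
    Z <- matrix(stats::rnorm(2 * N * d), 2 * N, d)
    expect_lt(abs(nt_xent_loss(Z, tau) - ntxent_oracle(Z, tau)), 1e-9)
  }
  expect_identical(nt_xent_loss(matrix(stats::rnorm(8), 2, 4), 0.7), 0)

  # permuting pair order leaves the loss unchanged
  Z <- matrix(stats::rnorm(8 * 5), 8, 5)
  perm_pairs <- c(5, 6, 1, 2, 7, 8, 3, 4)
  expect_equal(nt_xent_loss(Z, 0.3), nt_xent_loss(Z[perm_pairs, ], 0.3),
               tolerance = 1e-12)

  expect_gte(nt_xent_loss(Z, 0.5), 0)
  expect_error(nt_xent_loss(Z, tau = -1), "positive")
  expect_error(nt_xent_loss(Z[1:7, ], 0.5), "even")
  expect_error(contrastive_batch(matrix(0, 4, 3)), "non-zero")
})

test_that("analytic gradients match finite differences through the whole network", {
  withr::local_seed(3)
  ecfg <- encoder_config(64L, filters = c(4L, 6L), kernels = c(8L, 4L),
                         pool_size = 2L, dropout_rate = 0, dense_units = 5L,
                         l2_coeff = 0)
  pcfg <- projection_config(units = 7L)
  sh <- encoder_shapes(ecfg)
  params <- c(ecgclr:::.init_encoder_params(ecfg),
              build_projection(pcfg, sh$h_dim, seed = 3)$params)
  X <- matrix(stats::rnorm(6 * 64), 6, 64)
  loss_of <- function(pp) {
    fwd <- ecgclr:::.encoder_fwd(pp, ecfg, X)
    u <- ecgclr:::dense_forward(fwd$h, pp$proj_W, pp$proj_b)$out
    nt_xent_loss(ecgclr:::softmax_rows(u), tau = 0.5)
  }
  fwd <- ecgclr:::.encoder_fwd(params, ecfg, X, with_cache = TRUE)
  u <- ecgclr:::dense_forward(fwd$h, params$proj_W, params$proj_b)$out
  z <- ecgclr:::softmax_rows(u)
  nt <- nt_xent_loss(z, tau = 0.5, return_grad = TRUE)
  du <- z * (nt$grad - rowSums(nt$grad * z))
  pb <- ecgclr:::dense_backward(du, params$proj_W, fwd$h)
  grads <- ecgclr:::.encoder_bwd(params, ecfg, fwd$caches, pb$dh)
  grads$proj_W <- pb$dW
  grads$proj_b <- pb$db

  eps <- 1e-6
  worst <- 0
  for (nm in names(params)) {
    pick <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
    for (ii in pick) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      worst <- max(worst, abs(num - grads[[nm]][ii]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("pretraining ignores labels and records one loss per epoch", {
  segs <- make_sine_segments(24, 128, seed = 5)
  spec <- augmentation_spec(c("timewarp", "scale"))
  tcfg <- train_config(1e-3, 8L, 3L, 0.1, seed = 21)
  cfg <- tiny_encoder_cfg()
  pre <- pretrain(segs, spec, ecfg = cfg, pcfg = projection_config(8L), tcfg = tcfg)
  expect_length(pre$loss_history, 3)
  expect_true(all(is.finite(pre$loss_history)))

  shuffled <- segs
  shuffled$labels <- sample(segs$labels)
  pre2 <- pretrain(shuffled, spec, ecfg = cfg, pcfg = projection_config(8L), tcfg = tcfg)
  expect_identical(pre$loss_history, pre2$loss_history)
  expect_identical(pre$weights$params, pre2$weights$params)

  expect_error(pretrain(segs, spec, ecfg = cfg,
                        tcfg = train_config(1e-3, 1L, 2L)), "batch_size")
})

test_that("encoder weight shapes are invariant to batch size and augmentation", {
  segs <- make_sine_segments(20, 128, seed = 9)
  cfg <- tiny_encoder_cfg()
  p1 <- pretrain(segs, augmentation_spec("negate"), ecfg = cfg,
                 pcfg = projection_config(8L), tcfg = train_config(1e-3, 4L, 1L))
  p2 <- pretrain(segs, augmentation_spec(c("permute", "hflip")), ecfg = cfg,
                 pcfg = projection_config(8L), tcfg = train_config(1e-3, 10L, 1L))
  expect_identical(lapply(p1$weights$params, dim), lapply(p2$weights$params, dim))
})
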