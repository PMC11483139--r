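test_that("mmd is a symmetric nonnegative set statistic, zero on equality", {
  set.seed(1)
  a <- matrix(rnorm(40), 10, 4)
  b <- matrix(rnorm(40), 10, 4)
  expect_equal(mmd(a, a), 0)
  expect_equal(mmd(a, b), mmd(b, a), tolerance = 1e-12)
  expect_gte(mmd(a, b), 0)
  expect_equal(mmd(a[sample(10), ], b), mmd(a, b), tolerance = 1e-12)
  expect_error(mmd(a, b[, 1:3]), "mismatch")
})

test_that("mmd equals the brute-force double-sum kernel computation", {
  for (s in 1:5) {
    set.seed(s)
    m <- sample(3:20, 1)
    mp <- sample(3:20, 1)
    d <- sample(1:4, 1)
    a <- matrix(rnorm(m * d), m, d)
    b <- matrix(rnorm(mp * d), mp, d)
    scales <- runif(2, 0.5, 2)
    expect_equal(mmd(a, b, scales), max(bf_mmd(a, b, scales), 0),
                 tolerance = 1e-9)
  }
})

test_that("mmd separates a shifted distribution from a matched one", {
  wins <- sapply(1:10, function(s) {
    set.seed(s)
    a <- matrix(rnorm(500 * 3), 500, 3)
    b0 <- matrix(rnorm(500 * 3), 500, 3)
    b5 <- matrix(rnorm(500 * 3, mean = 5), 500, 3)
    scales <- c(1, 2)
    mmd(a, b0, scales) < mmd(a, b5, scales)
  })
  expect_true(all(wins))
})

test_that("xvae_loss decomposes exactly and matches hand arithmetic", {
  x1 <- matrix(c(0.1, 0.4, 0.2, 0.9, 0.5, 0.3), 2, 3)
  x2 <- matrix(c(0.7, 0.2, 0.6, 0.1, 0.8, 0.4), 2, 3)
  r1 <- x1 + 0.1
  r2 <- x2 - 0.2
  z <- matrix(c(0.5, -0.5, 1, 0), 2, 2)
  pz <- matrix(c(0, 1, -1, 0.5), 2, 2)
  l <- xvae_loss(x1, x2, r1, r2, z, pz, beta = 2, kernel_scales = 1)
  ## reconstruction: mean over the 2 samples of feature-summed squares
  expect_equal(l$recon, (6 * 0.1^2) / 2 + (6 * 0.2^2) / 2, tolerance = 1e-12)
  expect_equal(l$mmd, bf_mmd(z, pz, 1), tolerance = 1e-12)
  expect_equal(l$total, l$recon + 2 * l$mmd, tolerance = 1e-12)
  ## degenerate cases
  l0 <- xvae_loss(x1, x2, x1, x2, z, z, beta = 1)
  expect_equal(l0$total, 0)
  lb0 <- xvae_loss(x1, x2, r1, r2, z, pz, beta = 0)
  expect_equal(lb0$total, lb0$recon)
})

test_that("build_xvae honours the shape contract and seeded initialisation", {
  cfg <- xvae_config(view_hidden = 12L, fused_hidden = 10L, latent_dim = 16L,
                     seed = 5L)
  m <- build_xvae(50, 50, cfg)
  d <- tiny_data(seed = 1, n = 20, p = 50, q = 50)
  post <- encode(m, d$view1, d$view2)
  expect_equal(dim(post$mean), c(20L, 16L))
  expect_equal(dim(post$log_var), c(20L, 16L))
  rec <- reconstruct(m, d$view1, d$view2)
  expect_equal(dim(rec$x1), c(20L, 50L))
  expect_equal(dim(rec$x2), c(20L, 50L))
  m2 <- build_xvae(50, 50, cfg)
  expect_identical(m$params, m2$params)
  expect_error(build_xvae(0, 50, cfg), "positive")
  expect_error(encode(m, d$view1[, 1:10], d$view2), "widths")
})

test_that("analytic gradients match finite differences on a small model", {
  ns <- asNamespace("deconvae")
  cfg <- xvae_config(view_hidden = 5L, fused_hidden = 4L, latent_dim = 3L,
                     seed = 3L)
  model <- build_xvae(6, 7, cfg)
  set.seed(10)
  X1 <- matrix(runif(4 * 6), 4, 6)
  X2 <- matrix(runif(4 * 7), 4, 7)
  eps <- matrix(rnorm(12), 4, 3)
  prior <- matrix(rnorm(12), 4, 3)
  scales <- c(0.8, 1.5)
  lossfun <- function(params) {
    m2 <- model
    m2$params <- params
    fw <- ns$xvae_fwd(m2, X1, X2, NULL, eps)
    sum((X1 - fw$x1r)^2) / 4 + sum((X2 - fw$x2r)^2) / 4 +
      mmd(fw$z, prior, scales)
  }
  fw <- ns$xvae_fwd(model, X1, X2, NULL, eps)
  g <- ns$xvae_bwd(model, X1, X2, NULL, fw,
                   gz_extra = ns$mmd_grad_z(fw$z, prior, scales))
  for (nm in names(model$params)) {
    for (pn in names(model$params[[nm]])) {
      P0 <- model$params[[nm]][[pn]]
      set.seed(20)
      for (i in sample(length(P0), min(4, length(P0)))) {
        e <- 1e-6
        pp <- model$params
        pp[[nm]][[pn]][i] <- P0[i] + e
        pm <- model$params
        pm[[nm]][[pn]][i] <- P0[i] - e
        expect_equal(g[[nm]][[pn]][i], (lossfun(pp) - lossfun(pm)) / (2 * e),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces validation loss, is deterministic, improves RE", {
  d <- tiny_data(seed = 4, n = 200, p = 20, q = 20, signal = 1.5)
  cfg <- tiny_cfg(seed = 7L, epochs = 15L)
  m0 <- build_xvae(20, 20, cfg)
  m <- train_xvae(m0, d)
  expect_lt(m$history$val_total[nrow(m$history)], m$history$val_total[1])
  m2 <- train_xvae(build_xvae(20, 20, cfg), d)
  expect_identical(m$history, m2$history)
  rec0 <- reconstruct(m0, d$view1, d$view2)
  rec1 <- reconstruct(m, d$view1, d$view2)
  expect_lt(relative_error_combined(d$view1, rec1$x1, d$view2, rec1$x2),
            relative_error_combined(d$view1, rec0$x1, d$view2, rec0$x2))
  expect_true(all(m$history$train_recon >= 0))
  expect_true(all(m$history$train_mmd >= 0))
})

test_that("sample_latent follows the reparameterisation contract", {
  set.seed(2)
  post <- structure(list(mean = matrix(rnorm(15), 5, 3),
                         log_var = matrix(-1, 5, 3)),
                    class = "latent_posterior")
  draws <- sample_latent(post, n_draws = 50, seed = 9)
  expect_length(draws, 50)
  expect_true(all(vapply(draws, function(z) all(dim(z) == c(5, 3)), TRUE)))
  expect_identical(draws, sample_latent(post, n_draws = 50, seed = 9))
  ## degenerate variance: draws equal the mean to 6 decimals
  post$log_var[] <- -30
  dg <- sample_latent(post, n_draws = 2, seed = 1)
  expect_equal(dg[[1]], post$mean, tolerance = 1e-6)
  ## CLT: the mean of many draws approaches the posterior mean
  post$log_var[] <- 0
  big <- sample_latent(post, n_draws = 1e4, seed = 3)
  avg <- Reduce(`+`, big) / length(big)
  expect_true(max(abs(avg - post$mean)) < 4 / sqrt(1e4) * 1.5)
})
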