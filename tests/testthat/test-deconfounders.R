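test_that("encode_confounders produces the documented blocks", {
  f <- factor(sample(rep_len(1:6, 10)))
  E <- encode_confounders(f)
  expect_equal(dim(E), c(10L, 6L))
  expect_true(all(rowSums(E) == 1))
  cnum <- draw_numeric_confounder(10, seed = 1)
  En <- encode_confounders(cnum)
  expect_equal(mean(En), 0, tolerance = 1e-9)
  expect_equal(sd(En), 1, tolerance = 1e-9)
  Em <- encode_confounders(list(age = cnum, batch = f))
  expect_equal(ncol(Em), 7L)
  expect_error(encode_confounders(cnum, schemes = "bogus"), "scheme")
})

test_that("cXVAE carries conditioning blocks of the contracted widths", {
  cfg <- xvae_config(view_hidden = 12L, fused_hidden = 10L, latent_dim = 16L,
                     seed = 2L)
  enc <- encode_confounders(factor(rep_len(1:6, 30)))
  m <- build_cxvae(50, 50, cfg, enc, level = "input_embed")
  ## effective encoder view input width p + m = 56, decoder input d + m = 22
  expect_equal(dim(m$params$c_enc1a$W), c(6L, 12L))
  expect_equal(dim(m$params$c_enc1b$W), c(6L, 12L))
  expect_equal(dim(m$params$c_dfuse$W), c(6L, 10L))
  expect_identical(m$cond$level, "input_embed")
  mf <- build_cxvae(50, 50, cfg, enc, level = "fused")
  expect_equal(dim(mf$params$c_fuse$W), c(6L, 10L))
  expect_error(build_cxvae(50, 50, cfg, enc, level = "nope"))
  ## the underlying XVAE is initialised exactly as the unconditional one
  base <- build_xvae(50, 50, cfg)
  expect_identical(m$params[names(base$params)], base$params)
})

test_that("disabled deconfounding reproduces the vanilla trajectory exactly", {
  d <- tiny_data(seed = 5, n = 200, p = 15, q = 15)
  cfg <- tiny_cfg(seed = 11L, epochs = 6L)
  h0 <- train_xvae(build_xvae(15, 15, cfg), d)$history
  ## cXVAE with a zeroed conditioning matrix
  hz <- train_xvae(build_cxvae(15, 15, cfg, matrix(0, 200, 6)), d)$history
  expect_identical(h0, hz)
  cf <- factor(draw_numeric_confounder(200, seed = 3))
  ha <- train_adv_xvae(build_xvae(15, 15, cfg), d, cf,
                       adv = adversary_config(lambda_adv = 0,
                                              pretrain_epochs = 2L))$history
  expect_equal(h0$val_total, ha$val_total, tolerance = 1e-12)
  expect_equal(h0$train_total, ha$train_total, tolerance = 1e-12)
  hr <- train_cr_xvae(build_xvae(15, 15, cfg), d, as.numeric(cf),
                      spec = cr_penalty_spec("sq_corr", lambda_cr = 0))$history
  expect_equal(h0$val_total, hr$val_total, tolerance = 1e-12)
})

test_that("cr_penalty matches its contract on constructed cases", {
  set.seed(8)
  cc <- as.numeric(draw_numeric_confounder(200, seed = 2))
  ## a latent dim equal to the confounder has r = 1
  z <- cbind(cc, matrix(rnorm(200 * 3), 200, 3))
  expect_equal(cr_penalty(z, cc, cr_penalty_spec("sq_corr")),
               cr_penalty(cbind(cc), cc, cr_penalty_spec("sq_corr")) / 4 +
                 cr_penalty(z[, -1], cc, cr_penalty_spec("sq_corr")) * 3 / 4,
               tolerance = 1e-12)
  expect_equal(cr_penalty(cbind(cc), cc, cr_penalty_spec("sq_corr")), 1)
  expect_equal(cr_penalty(cbind(cc), cc, cr_penalty_spec("abs_corr")), 1)
  ## independent latents: small penalty
  z0 <- matrix(rnorm(1000 * 8), 1000, 8)
  expect_lt(cr_penalty(z0, as.numeric(draw_numeric_confounder(1000, seed = 4)),
                       cr_penalty_spec("abs_corr")), 0.1)
  ## r^2 <= |r| per dimension
  for (j in 1:4) {
    a <- cr_penalty(z[, j, drop = FALSE], cc, cr_penalty_spec("abs_corr"))
    s <- cr_penalty(z[, j, drop = FALSE], cc, cr_penalty_spec("sq_corr"))
    expect_lte(s, a + 1e-12)
  }
  ## zero-variance dimension contributes zero
  expect_equal(cr_penalty(cbind(rep(1, 200)), cc, cr_penalty_spec("sq_corr")), 0)
  expect_error(cr_penalty(z[1:2, ], cc[1:2]), "n >= 3")
})

test_that("mutual-information penalties detect dependence and have exact gradients", {
  ns <- asNamespace("deconvae")
  set.seed(3)
  cc <- draw_numeric_confounder(150, seed = 6)
  z_dep <- cbind(cc + rnorm(150, sd = 0.3))
  z_ind <- cbind(rnorm(150))
  for (m in c("mi_histogram", "mi_kde")) {
    spec <- cr_penalty_spec(m)
    expect_gt(cr_penalty(z_dep, cc, spec), cr_penalty(z_ind, cc, spec))
  }
  ## gradient of the KDE variant at fixed bandwidth vs finite differences
  x <- rnorm(30)
  cl <- ns$confounder_classes(sample(1:3, 30, TRUE))
  res <- ns$mi_kde_1d(x, cl, bandwidth = 0.5)
  for (i in c(1, 7, 30)) {
    e <- 1e-6
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    fd <- (ns$mi_kde_1d(xp, cl, 0.5, FALSE)$value -
             ns$mi_kde_1d(xm, cl, 0.5, FALSE)$value) / (2 * e)
    expect_equal(res$grad[i], fd, tolerance = 1e-5)
  }
  ## soft-histogram gradient (interior points; bin edges are stop-gradient)
  res2 <- ns$mi_hist_1d(x, cl, bins = 8)
  interior <- setdiff(seq_along(x), c(which.min(x), which.max(x)))[1:3]
  for (i in interior) {
    e <- 1e-6
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    fd <- (ns$mi_hist_1d(xp, cl, 8, FALSE)$value -
             ns$mi_hist_1d(xm, cl, 8, FALSE)$value) / (2 * e)
    expect_equal(res2$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("cr training lowers the latent-confounder correlation", {
  ## averaged over seeds on linearly confounded data
  diffs <- sapply(1:5, function(s) {
    d <- tiny_data(seed = s, n = 200, p = 15, q = 15, signal = 1)
    cc <- draw_numeric_confounder(200, seed = s + 20)
    cd <- apply_effects(d, linear_effect(200, 15, 15, cc, seed = s + 40))
    cfg <- tiny_cfg(seed = s, epochs = 15L)
    mean_abs_r <- function(m) {
      z <- encode(m, cd$confounded1, cd$confounded2)$mean
      mean(abs(suppressWarnings(cor(z, cc))), na.rm = TRUE)
    }
    m0 <- train_xvae(build_xvae(15, 15, cfg), cd)
    m1 <- train_cr_xvae(build_xvae(15, 15, cfg), cd, as.numeric(cc),
                        spec = cr_penalty_spec("sq_corr", lambda_cr = 5))
    mean_abs_r(m0) - mean_abs_r(m1)
  })
  expect_gt(mean(diffs), 0)
  ## penalty log is nonnegative throughout
  d <- tiny_data(seed = 1, n = 200, p = 15, q = 15)
  cc <- draw_numeric_confounder(200, seed = 1)
  m <- train_cr_xvae(build_xvae(15, 15, tiny_cfg(seed = 2, epochs = 5L)), d,
                     as.numeric(cc))
  expect_true(all(m$history$train_penalty >= 0))
})

test_that("the adversary learns the confounder and training weakens it", {
  ns <- asNamespace("deconvae")
  ## freshly trained probe, fit on one half, scored on the held-out half
  probe_acc <- function(model, cd, y) {
    z <- encode(model, cd$confounded1, cd$confounded2)$mean
    cl <- ns$confounder_classes(y)
    set.seed(1)
    tr <- sample(nrow(z), nrow(z) / 2)
    net <- ns$adversary_build(ncol(z), cl$K, 16L)
    st <- ns$adam_init(net)
    for (ep in 1:150) {
      fw <- ns$adversary_fwd(net, z[tr, ])
      bw <- ns$adversary_bwd(net, z[tr, ], fw, cl$y[tr])
      upd <- ns$adam_step(net, bw$grads, st, lr = 5e-3)
      net <- upd$params
      st <- upd$state
    }
    mean(max.col(ns$adversary_fwd(net, z[-tr, ])$p) == cl$y[-tr])
  }
  accs <- sapply(1:10, function(s) {
    d <- tiny_data(seed = s, n = 400, p = 40, q = 40, k = 6, signal = 1.5)
    eff <- categorical_effect(400, 40, 40, seed = s + 30)
    cd <- apply_effects(d, eff)
    y <- factor(eff$confounder_label)
    cfg <- xvae_config(view_hidden = 64L, fused_hidden = 64L,
                       latent_dim = 16L, epochs = 40L,
                       learning_rate = 5e-3, early_stop_patience = 20L,
                       seed = s + 7)
    m0 <- train_xvae(build_xvae(40, 40, cfg), cd)
    ma <- train_adv_xvae(build_xvae(40, 40, cfg), cd, y,
                         adv = adversary_config(pretrain_epochs = 5L,
                                                lambda_adv = 2))
    c(vanilla = probe_acc(m0, cd, y), adv = probe_acc(ma, cd, y))
  })
  ## confounder is decodable from vanilla embeddings well above chance
  expect_gt(mean(accs["vanilla", ]), 1 / 6)
  ## adversarial training reduces probe accuracy on average
  expect_lt(mean(accs["adv", ]), mean(accs["vanilla", ]))
  expect_error(
    train_adv_xvae(build_xvae(20, 20, tiny_cfg()), tiny_data(n = 200L, p = 20, q = 20),
                   runif(200)),
    "discrete")
})

test_that("filter_latent_features applies thresholds per criterion", {
  cc <- as.numeric(draw_numeric_confounder(300, seed = 2))
  z_copy <- cc
  z_04 <- make_correlated(cc, 0.4, seed = 3)
  z_ind <- make_correlated(cc, 0.0, seed = 4)
  Z <- cbind(z_copy, z_04, z_ind)
  expect_identical(filter_latent_features(Z, cc, fs_criterion("pvalue", 0.05)), 3L)
  expect_identical(filter_latent_features(Z, cc, fs_criterion("abs_corr", 0.3)), 3L)
  expect_identical(filter_latent_features(Z, cc, fs_criterion("abs_corr", 0.5)),
                   c(2L, 3L))
  ## all-removed fallback keeps the least correlated dim with a warning
  expect_warning(
    keep <- filter_latent_features(cbind(cc, 0.9 * cc + 0.1 * z_ind), cc,
                                   fs_criterion("abs_corr", 0.3)),
    "retaining")
  expect_length(keep, 1L)
  ## removal rule: violating for any confounder removes the dim
  c2 <- as.numeric(draw_numeric_confounder(300, seed = 9))
  z2 <- make_correlated(c2, 0.6, seed = 10)
  expect_identical(
    filter_latent_features(cbind(z2, z_ind), list(cc, c2),
                           fs_criterion("abs_corr", 0.5)),
    2L)
})

test_that("lr_pca baseline residualises, preserves geometry, clusters", {
  ## purely linear confounding with no other signal: residuals vanish
  cc <- draw_numeric_confounder(80, seed = 1)
  e <- linear_effect(80, 6, 5, cc, seed = 2)
  res <- lr_pca_baseline(e$E1, e$E2, as.numeric(cc), n_pcs = 4, k = 2, seed = 1)
  expect_lt(max(abs(res$residuals)), 1e-8)
  ## confounder orthogonal to the data: cluster recovery unharmed
  d <- tiny_data(seed = 6, n = 200, p = 20, q = 20, k = 4, signal = 2)
  rnd <- as.numeric(draw_numeric_confounder(200, seed = 7))
  base <- lr_pca_baseline(d$view1, d$view2, list(), n_pcs = 10, k = 4, seed = 3)
  corr <- lr_pca_baseline(d$view1, d$view2, rnd, n_pcs = 10, k = 4, seed = 3)
  expect_lt(abs(ari(base$labels, d$true_labels) -
                  ari(corr$labels, d$true_labels)), 0.05)
  ## full-rank PCA is a rotation: pairwise distances preserved
  full <- lr_pca_baseline(d$view1, d$view2, rnd, n_pcs = 200, k = 4, seed = 3)
  Rm <- cbind(qr.resid(qr(cbind(1, rnd)), d$view1),
              qr.resid(qr(cbind(1, rnd)), d$view2))
  expect_equal(as.matrix(dist(full$embedding)),
               as.matrix(dist(Rm)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(lr_pca_baseline(d$view1[1:2, ], d$view2[1:2, ],
                               list(a = rnd[1:2], b = rnd[1:2] * 2), k = 2),
               "covariates")
})

test_that("lr_pca baseline handles an empty confounder list", {
  d <- tiny_data(seed = 1, n = 60, p = 8, q = 8, k = 3, signal = 3)
  res <- lr_pca_baseline(d$view1, d$view2, list(), n_pcs = 5, k = 3, seed = 2)
  expect_gt(ari(res$labels, d$true_labels), 0.8)
  expect_equal(ncol(res$embedding), 5L)
})
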