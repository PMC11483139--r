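#' Configuration for XVAE-family models
#'
#' @param view_hidden Width of the per-view first encoder layer.
#' @param fused_hidden Width of the fusion layer.
#' @param latent_dim Latent dimensionality (50 at full scale, to match the
#'   50-PC baseline embedding; tests use 16).
#' @param beta Weight of the MMD regulariser in the loss (default 1).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (best weights are restored).
#' @param val_fraction Fraction of samples held out for validation
#'   monitoring (the 80:20 split).
#' @param seed Integer seed governing initialisation, the split, batch
#'   order, and all sampling during training.
#' @return A list of class `xvae_config`.
#' @export
xvae_config <- function(view_hidden = 128L, fused_hidden = 128L,
                        latent_dim = 50L, beta = 1,
                        epochs = 100L, batch_size = 64L,
                        learning_rate = 1e-3, early_stop_patience = 10L,
                        val_fraction = 0.2, seed = 1L) {
  if (latent_dim < 1) stopf("latent_dim must be >= 1")
  if (beta < 0) stopf("beta must be >= 0")
  if (val_fraction <= 0 || val_fraction >= 1) stopf("val_fraction must be in (0, 1)")
  if (view_hidden < 1 || fused_hidden < 1) stopf("hidden widths must be positive")
  structure(list(view_hidden = as.integer(view_hidden),
                 fused_hidden = as.integer(fused_hidden),
                 latent_dim = as.integer(latent_dim), beta = beta,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "xvae_config")
}

#' Build an X-shaped variational autoencoder
#'
#' Two per-view encoder branches (`x1 -> h1a`, `x2 -> h1b`) are fused into
#' a shared hidden layer, from which linear heads produce the latent mean
#' and log-variance; the decoder mirrors the structure (`z -> fused' ->
#' h1a'/h1b' -> x1'/x2'`). Hidden layers use ReLU, outputs are linear.
#' Initialisation (He-scaled Gaussians) is deterministic given
#' `cfg$seed`, with a documented draw order: enc1a, enc1b, fuse, mu,
#' log-var, dfuse, dh1a, dh1b, out1, out2.
#'
#' @param p,q Input widths of the two views.
#' @param cfg An [xvae_config()].
#' @return Object of class `xvae` holding the parameters, configuration
#'   and (after training) a loss history.
#' @export
build_xvae <- function(p, q, cfg) {
  if (p < 1 || q < 1) stopf("input widths must be positive")
  stopifnot(inherits(cfg, "xvae_config"))
  h1 <- cfg$view_hidden
  h2 <- cfg$fused_hidden
  d <- cfg$latent_dim
  params <- with_seed(cfg$seed, list(
    enc1a = init_dense(p, h1),
    enc1b = init_dense(q, h1),
    fuse = init_dense(2L * h1, h2),
    mu = init_dense(h2, d),
    lv = init_dense(h2, d),
    dfuse = init_dense(d, h2),
    dh1a = init_dense(h2, h1),
    dh1b = init_dense(h2, h1),
    out1 = init_dense(h1, p),
    out2 = init_dense(h1, q)
  ))
  structure(list(p = as.integer(p), q = as.integer(q), cfg = cfg,
                 params = params,
                 cond = list(level = "none", m = 0L, matrix = NULL),
                 trained = FALSE, history = NULL),
            class = "xvae")
}

#' @export
print.xvae <- function(x, ...) {
  cat(sprintf("%s: p=%d, q=%d, hidden=%d/%d, latent=%d, cond=%s%s\n",
              class(x)[1], x$p, x$q, x$cfg$view_hidden, x$cfg$fused_hidden,
              x$cfg$latent_dim, x$cond$level,
              if (x$trained) sprintf(", trained (%d epochs)", nrow(x$history)) else ""))
  invisible(x)
}

## conditioning rows for a set of sample indices (NULL when unconditioned)
cond_rows <- function(model, idx) {
  if (is.null(model$cond$matrix)) return(NULL)
  model$cond$matrix[idx, , drop = FALSE]
}

## Forward pass. C is the conditioning block for these rows (or NULL);
## eps NULL means z = mu (posterior mean path).
xvae_fwd <- function(model, X1, X2, C = NULL, eps = NULL) {
  pp <- model$params
  lev <- model$cond$level
  pre1a <- dense_fwd(pp$enc1a, X1)
  pre1b <- dense_fwd(pp$enc1b, X2)
  if (!is.null(C) && lev %in% c("input", "input_embed")) {
    pre1a <- pre1a + C %*% pp$c_enc1a$W
    pre1b <- pre1b + C %*% pp$c_enc1b$W
  }
  h1a <- relu(pre1a)
  h1b <- relu(pre1b)
  f_in <- cbind(h1a, h1b)
  pref <- dense_fwd(pp$fuse, f_in)
  if (!is.null(C) && lev == "fused") pref <- pref + C %*% pp$c_fuse$W
  fused <- relu(pref)
  mu <- dense_fwd(pp$mu, fused)
  lv <- dense_fwd(pp$lv, fused)
  z <- if (is.null(eps)) mu else mu + exp(lv / 2) * eps
  predf <- dense_fwd(pp$dfuse, z)
  if (!is.null(C) && lev %in% c("embed", "input_embed")) {
    predf <- predf + C %*% pp$c_dfuse$W
  }
  df <- relu(predf)
  pre_o1 <- dense_fwd(pp$dh1a, df)
  pre_o2 <- dense_fwd(pp$dh1b, df)
  dh1a <- relu(pre_o1)
  dh1b <- relu(pre_o2)
  x1r <- dense_fwd(pp$out1, dh1a)
  x2r <- dense_fwd(pp$out2, dh1b)
  list(pre1a = pre1a, pre1b = pre1b, h1a = h1a, h1b = h1b, f_in = f_in,
       pref = pref, fused = fused, mu = mu, lv = lv, z = z, eps = eps,
       predf = predf, df = df, pre_o1 = pre_o1, pre_o2 = pre_o2,
       dh1a = dh1a, dh1b = dh1b, x1r = x1r, x2r = x2r)
}

## Backward pass. gz_extra: gradient w.r.t. z from MMD / penalties.
## Returns gradients for every parameter block.
xvae_bwd <- function(model, X1, X2, C, fw, gz_extra = NULL) {
  pp <- model$params
  lev <- model$cond$level
  nb <- nrow(X1)
  g <- list()
  d1 <- 2 * (fw$x1r - X1) / nb
  d2 <- 2 * (fw$x2r - X2) / nb
  b1 <- dense_bwd(pp$out1, fw$dh1a, d1)
  g$out1 <- b1[c("dW", "db")]
  del_o1 <- b1$dX * (fw$pre_o1 > 0)
  b2 <- dense_bwd(pp$out2, fw$dh1b, d2)
  g$out2 <- b2[c("dW", "db")]
  del_o2 <- b2$dX * (fw$pre_o2 > 0)
  ba <- dense_bwd(pp$dh1a, fw$df, del_o1)
  g$dh1a <- ba[c("dW", "db")]
  bb <- dense_bwd(pp$dh1b, fw$df, del_o2)
  g$dh1b <- bb[c("dW", "db")]
  del_df <- (ba$dX + bb$dX) * (fw$predf > 0)
  bf <- dense_bwd(pp$dfuse, fw$z, del_df)
  g$dfuse <- bf[c("dW", "db")]
  if (!is.null(C) && lev %in% c("embed", "input_embed")) {
    g$c_dfuse <- list(W = crossprod(C, del_df))
  }
  gz <- bf$dX
  if (!is.null(gz_extra)) gz <- gz + gz_extra
  dmu <- gz
  dlv <- if (is.null(fw$eps)) matrix(0, nrow(gz), ncol(gz)) else
    gz * fw$eps * 0.5 * exp(fw$lv / 2)
  bm <- dense_bwd(pp$mu, fw$fused, dmu)
  g$mu <- bm[c("dW", "db")]
  bl <- dense_bwd(pp$lv, fw$fused, dlv)
  g$lv <- bl[c("dW", "db")]
  del_fused <- (bm$dX + bl$dX) * (fw$pref > 0)
  bfu <- dense_bwd(pp$fuse, fw$f_in, del_fused)
  g$fuse <- bfu[c("dW", "db")]
  if (!is.null(C) && lev == "fused") {
    g$c_fuse <- list(W = crossprod(C, del_fused))
  }
  h1 <- model$cfg$view_hidden
  dh1a_in <- bfu$dX[, seq_len(h1), drop = FALSE]
  dh1b_in <- bfu$dX[, h1 + seq_len(h1), drop = FALSE]
  del_1a <- dh1a_in * (fw$pre1a > 0)
  del_1b <- dh1b_in * (fw$pre1b > 0)
  be1 <- dense_bwd(pp$enc1a, X1, del_1a)
  g$enc1a <- be1[c("dW", "db")]
  be2 <- dense_bwd(pp$enc1b, X2, del_1b)
  g$enc1b <- be2[c("dW", "db")]
  if (!is.null(C) && lev %in% c("input", "input_embed")) {
    g$c_enc1a <- list(W = crossprod(C, del_1a))
    g$c_enc1b <- list(W = crossprod(C, del_1b))
  }
  ## rename dW/db -> W/b so grads align with parameter lists
  lapply(g, function(x) {
    names(x) <- sub("^d", "", names(x))
    x
  })
}

#' XVAE loss: reconstruction error plus MMD regulariser
#'
#' The reconstruction term is the per-sample mean of squared errors summed
#' over features (Gaussian log-likelihood up to constants), with both
#' views weighted equally; the regulariser is `beta` times the [mmd()]
#' between the sampled latents and draws from the standard Gaussian prior.
#'
#' @param x1,x2 Input minibatches (rows are samples).
#' @param recon1,recon2 Reconstructions with matching shapes.
#' @param z_samples Sampled latent codes for the batch.
#' @param prior_samples Draws from the prior, same dimension.
#' @param beta Regulariser weight.
#' @param kernel_scales Optional MMD bandwidths (default: median
#'   heuristic).
#' @return List with `total`, `recon` and `mmd` (unweighted) components;
#'   `total = recon + beta * mmd` exactly.
#' @export
xvae_loss <- function(x1, x2, recon1, recon2, z_samples, prior_samples,
                      beta = 1, kernel_scales = NULL) {
  nb <- nrow(as.matrix(x1))
  recon <- sum((x1 - recon1)^2) / nb + sum((x2 - recon2)^2) / nb
  m <- mmd(z_samples, prior_samples, kernel_scales)
  list(total = recon + beta * m, recon = recon, mmd = m)
}

flat_params <- function(model) {
  model$params
}

## Core minibatch trainer shared by all XVAE variants.
## penalty(z, idx): extra loss term (already weighted), returning
##   list(value, grad) with grad the gradient w.r.t. z (or NULL).
## hook(model, epoch): side-channel trainer (adversary); called after each
##   epoch >= hook_from, with the main RNG stream shielded.
train_core <- function(model, X1, X2, penalty = NULL, penalty_from = 1L,
                       hook = NULL, hook_from = 1L, hook_env = NULL) {
  cfg <- model$cfg
  n <- nrow(X1)
  if (n < cfg$batch_size) stopf("need n >= batch_size (%d < %d)", n, cfg$batch_size)
  with_seed(cfg$seed, {
    n_val <- max(1L, round(cfg$val_fraction * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    d <- cfg$latent_dim
    state <- adam_init(model$params)
    best_val <- Inf
    best_params <- model$params
    wait <- 0L
    hist <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(tr_idx)
      starts <- seq(1L, length(perm), by = cfg$batch_size)
      tr_tot <- tr_rec <- tr_mmd <- tr_pen <- 0
      nb_used <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, length(perm))]
        nb <- length(idx)
        if (nb < 2L) next
        eps <- matrix(stats::rnorm(nb * d), nb, d)
        prior <- matrix(stats::rnorm(nb * d), nb, d)
        x1 <- X1[idx, , drop = FALSE]
        x2 <- X2[idx, , drop = FALSE]
        C <- cond_rows(model, idx)
        fw <- xvae_fwd(model, x1, x2, C, eps)
        scales <- mmd_default_scales(fw$z, prior)
        mmd_val <- mmd(fw$z, prior, scales)
        gz <- cfg$beta * mmd_grad_z(fw$z, prior, scales)
        pen <- list(value = 0, grad = NULL)
        if (!is.null(penalty) && epoch >= penalty_from) {
          pen <- penalty(fw$z, idx)
          if (!is.null(pen$grad)) gz <- gz + pen$grad
        }
        recon <- sum((x1 - fw$x1r)^2) / nb + sum((x2 - fw$x2r)^2) / nb
        total <- recon + cfg$beta * mmd_val + pen$value
        if (!is.finite(total)) {
          stopf("training diverged at epoch %d (loss = %s); lower the learning rate",
                epoch, format(total))
        }
        g <- xvae_bwd(model, x1, x2, C, fw, gz_extra = gz)
        upd <- adam_step(model$params, g, state, lr = cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
        tr_tot <- tr_tot + total
        tr_rec <- tr_rec + recon
        tr_mmd <- tr_mmd + mmd_val
        tr_pen <- tr_pen + pen$value
        nb_used <- nb_used + 1L
      }
      ## validation pass (single sampled draw, main stream)
      eps_v <- matrix(stats::rnorm(n_val * d), n_val, d)
      prior_v <- matrix(stats::rnorm(n_val * d), n_val, d)
      x1v <- X1[val_idx, , drop = FALSE]
      x2v <- X2[val_idx, , drop = FALSE]
      fwv <- xvae_fwd(model, x1v, x2v, cond_rows(model, val_idx), eps_v)
      val_rec <- sum((x1v - fwv$x1r)^2) / n_val + sum((x2v - fwv$x2r)^2) / n_val
      val_mmd <- mmd(fwv$z, prior_v)
      val_pen <- 0
      if (!is.null(penalty) && epoch >= penalty_from) {
        val_pen <- penalty(fwv$z, val_idx)$value
      }
      val_tot <- val_rec + cfg$beta * val_mmd + val_pen
      hist[[epoch]] <- data.frame(
        epoch = epoch,
        train_total = tr_tot / nb_used, train_recon = tr_rec / nb_used,
        train_mmd = tr_mmd / nb_used, train_penalty = tr_pen / nb_used,
        val_total = val_tot, val_recon = val_rec, val_mmd = val_mmd,
        val_penalty = val_pen)
      if (!is.null(hook) && epoch >= hook_from) {
        main_state <- get_rng_state()
        set_rng_state(hook_env$rng)
        model <- hook(model, epoch, tr_idx)
        hook_env$rng <- get_rng_state()
        set_rng_state(main_state)
      }
      if (val_tot < best_val - 1e-9) {
        best_val <- val_tot
        best_params <- model$params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    model$params <- best_params
    model$trained <- TRUE
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
    model$split <- list(train = tr_idx, val = val_idx)
    model
  })
}

#' Train an XVAE
#'
#' Minibatch stochastic-gradient training (Adam) with reparameterised
#' latent sampling and a fresh prior batch per step for the MMD term.
#' An 80:20 train/validation split is drawn from `cfg$seed`; the
#' validation loss is monitored for early stopping and the best weights
#' are restored. Deterministic given `cfg$seed`.
#'
#' @param model An [build_xvae()] (or conditional variant) model.
#' @param data A `paired_omics` or `confounded_omics` object, or a list
#'   with matrices `X1`, `X2`.
#' @param cfg Optional [xvae_config()] overriding the one stored in the
#'   model.
#' @return The trained model; `$history` holds per-epoch train/validation
#'   loss components.
#' @export
train_xvae <- function(model, data, cfg = NULL) {
  stopifnot(inherits(model, "xvae"))
  if (!is.null(cfg)) model$cfg <- cfg
  v <- dataset_views(data)
  train_core(model, v$X1, v$X2)
}

#' Latent posterior, sampling and reconstruction
#'
#' `encode()` returns the per-sample latent posterior (mean and
#' log-variance); `sample_latent()` draws embedding matrices
#' `mean + exp(log_var / 2) * eps`, `eps ~ N(0, I)`; `reconstruct()`
#' decodes the posterior mean.
#'
#' @param model A (trained) `xvae` model.
#' @param x1,x2 View matrices aligned with the model; for conditional
#'   models the stored conditioning matrix must have matching rows.
#' @return `encode()`: object of class `latent_posterior` with `mean` and
#'   `log_var` (n x d); `sample_latent()`: list of `n_draws` n x d
#'   matrices; `reconstruct()`: list with `x1` and `x2` reconstructions.
#' @export
encode <- function(model, x1, x2) {
  stopifnot(inherits(model, "xvae"))
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  if (ncol(x1) != model$p || ncol(x2) != model$q) {
    stopf("encode: feature widths (%d, %d) do not match model (%d, %d)",
          ncol(x1), ncol(x2), model$p, model$q)
  }
  C <- cond_rows(model, seq_len(nrow(x1)))
  fw <- xvae_fwd(model, x1, x2, C, eps = NULL)
  structure(list(mean = fw$mu, log_var = fw$lv), class = "latent_posterior")
}

#' @rdname encode
#' @param post A `latent_posterior`.
#' @param n_draws Number of embedding matrices to sample.
#' @param seed Integer seed.
#' @export
sample_latent <- function(post, n_draws = 50L, seed = 1L) {
  stopifnot(inherits(post, "latent_posterior"))
  n <- nrow(post$mean)
  d <- ncol(post$mean)
  sdm <- exp(post$log_var / 2)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      post$mean + sdm * matrix(stats::rnorm(n * d), n, d)
    })
  })
}

#' @rdname encode
#' @export
reconstruct <- function(model, x1, x2) {
  stopifnot(inherits(model, "xvae"))
  C <- cond_rows(model, seq_len(nrow(as.matrix(x1))))
  fw <- xvae_fwd(model, as.matrix(x1), as.matrix(x2), C, eps = NULL)
  list(x1 = fw$x1r, x2 = fw$x2r)
}
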