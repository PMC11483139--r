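#' Encode confounders as conditioning covariates
#'
#' Categorical confounders become one-hot blocks (row sums 1); numeric
#' ones become standardised scalars (mean 0, sd 1). Blocks are
#' concatenated column-wise in the order given. The standardised-scalar
#' encoding preserves ordinal information of discrete numeric confounders
#' (appropriate when the confounding effect is a function of the value);
#' one-hot matches class semantics of batch-like confounders.
#'
#' @param confounders A vector or a (optionally named) list of vectors,
#'   all of length n.
#' @param schemes Optional character vector, one of `"onehot"` or
#'   `"standardized_scalar"` per confounder; defaults to one-hot for
#'   factors/characters and standardised scalar for numerics.
#' @return A `confounder_encoding`: n x m numeric matrix with a
#'   `schemes` attribute.
#' @export
encode_confounders <- function(confounders, schemes = NULL) {
  if (!is.list(confounders)) confounders <- list(confounders)
  n <- length(confounders[[1]])
  if (is.null(schemes)) {
    schemes <- vapply(confounders, function(x) {
      if (is.numeric(x)) "standardized_scalar" else "onehot"
    }, "")
  }
  schemes <- rep_len(schemes, length(confounders))
  blocks <- mapply(function(x, sch, nm) {
    if (length(x) != n) stopf("confounder lengths differ")
    if (sch == "onehot") {
      f <- factor(x)
      B <- diag(nlevels(f))[as.integer(f), , drop = FALSE]
      colnames(B) <- paste0(nm, "_", levels(f))
      B
    } else if (sch == "standardized_scalar") {
      x <- as.numeric(x)
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) s <- 1
      B <- matrix((x - mean(x)) / s, ncol = 1)
      colnames(B) <- nm
      B
    } else {
      stopf("unknown encoding scheme '%s'", sch)
    }
  }, confounders, schemes,
  names(confounders) %||% paste0("conf", seq_along(confounders)),
  SIMPLIFY = FALSE)
  M <- do.call(cbind, blocks)
  structure(M, schemes = schemes, class = c("confounder_encoding", class(M)))
}

#' Build a conditional XVAE (cXVAE)
#'
#' An XVAE whose encoder and/or decoder receive the confounder covariates
#' as auxiliary inputs, so the latent space need not encode them.
#' Conditioning levels: `"input"` appends the covariates to each view's
#' encoder input, `"fused"` to the fusion-layer input, `"embed"` to the
#' latent code before the decoder, and `"input_embed"` to both encoder input and decoder input. The default
#' is `"embed"`: decoder-side conditioning relieves the latent code of
#' the confounder-explained variation, while encoder-side conditioning
#' lets the encoder copy the covariate block into the latent at no
#' reconstruction cost (see the methods vignette).
#'
#' The base architecture is initialised exactly like [build_xvae()] with
#' the same seed; the conditioning weight blocks are drawn from a derived
#' side stream, so a cXVAE whose conditioning matrix is all zeros trains
#' identically to the vanilla XVAE.
#'
#' @param p,q Input widths.
#' @param cfg An [xvae_config()].
#' @param enc A [encode_confounders()] matrix aligned with the training
#'   samples.
#' @param level Conditioning level (see above).
#' @return Object of class `c("cxvae", "xvae")`; train with
#'   [train_xvae()].
#' @export
build_cxvae <- function(p, q, cfg, enc,
                        level = c("embed", "input", "fused", "input_embed")) {
  level <- match.arg(level)
  enc <- as.matrix(enc)
  m <- ncol(enc)
  model <- build_xvae(p, q, cfg)
  h1 <- cfg$view_hidden
  h2 <- cfg$fused_hidden
  model$params <- c(model$params, with_seed(derive_seed(cfg$seed, 7L), {
    blocks <- list()
    if (level %in% c("input", "input_embed")) {
      blocks$c_enc1a <- matrix(stats::rnorm(m * h1, sd = sqrt(2 / m)), m, h1)
      blocks$c_enc1b <- matrix(stats::rnorm(m * h1, sd = sqrt(2 / m)), m, h1)
    }
    if (level == "fused") {
      blocks$c_fuse <- matrix(stats::rnorm(m * h2, sd = sqrt(2 / m)), m, h2)
    }
    if (level %in% c("embed", "input_embed")) {
      blocks$c_dfuse <- matrix(stats::rnorm(m * h2, sd = sqrt(2 / m)), m, h2)
    }
    ## wrap bare matrices as single-entry param lists for the optimiser
    lapply(blocks, function(W) list(W = W))
  }))
  ## adam_init/adam_step treat each block as {W}; forward indexes $W
  model$cond <- list(level = level, m = m, matrix = enc)
  class(model) <- c("cxvae", class(model))
  model
}

#' Adversary configuration for adv-XVAE
#'
#' @param hidden Width of the adversary MLP's hidden layer.
#' @param lambda_adv Weight of the adversarial term subtracted from the
#'   XVAE loss (>= 0).
#' @param pretrain_epochs Plain-XVAE epochs before alternation starts.
#' @param steps_per_alternation Adversary epochs per XVAE epoch.
#' @param learning_rate Adam learning rate of the adversary.
#' @return List of class `adversary_config`.
#' @export
adversary_config <- function(hidden = 32L, lambda_adv = 1,
                             pretrain_epochs = 10L,
                             steps_per_alternation = 1L,
                             learning_rate = 1e-3) {
  if (lambda_adv < 0) stopf("lambda_adv must be >= 0")
  structure(list(hidden = as.integer(hidden), lambda_adv = lambda_adv,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 steps_per_alternation = as.integer(steps_per_alternation),
                 learning_rate = learning_rate),
            class = "adversary_config")
}

adversary_build <- function(d, K, hidden) {
  list(l1 = init_dense(d, hidden), l2 = init_dense(hidden, K))
}

adversary_fwd <- function(net, Z) {
  pre <- dense_fwd(net$l1, Z)
  h <- relu(pre)
  logits <- dense_fwd(net$l2, h)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  p <- el / rowSums(el)
  list(pre = pre, h = h, logits = logits, p = p)
}

## multiclass cross-entropy and gradients; y integer in 1..K
adversary_ce <- function(fw, y) {
  nb <- length(y)
  -mean(log(pmax(fw$p[cbind(seq_len(nb), y)], 1e-12)))
}

## gradient of CE w.r.t. adversary weights and its input
adversary_bwd <- function(net, Z, fw, y) {
  nb <- length(y)
  dlog <- fw$p
  dlog[cbind(seq_len(nb), y)] <- dlog[cbind(seq_len(nb), y)] - 1
  dlog <- dlog / nb
  b2 <- dense_bwd(net$l2, fw$h, dlog)
  del1 <- b2$dX * (fw$pre > 0)
  b1 <- dense_bwd(net$l1, Z, del1)
  list(grads = list(l1 = list(W = b1$dW, b = b1$db),
                    l2 = list(W = b2$dW, b = b2$db)),
       dZ = b1$dX)
}

## discretise a confounder into integer classes 1..K
confounder_classes <- function(x) {
  if (is.numeric(x) && length(unique(x)) > 12L) {
    stopf(paste("continuous confounder: adversarial training needs discrete",
                "class levels; bin the confounder or pass a factor"))
  }
  f <- factor(x)
  list(y = as.integer(f), K = nlevels(f))
}

#' Train an adversarially deconfounded XVAE (adv-XVAE)
#'
#' Alternating optimisation: after `pretrain_epochs` of plain XVAE
#' training, each epoch (a) trains an adversary MLP to predict the
#' confounder classes from the (frozen) latent means by multiclass
#' cross-entropy, then (b) trains the XVAE on its loss minus
#' `lambda_adv` times the adversary's loss with the adversary frozen, so
#' the embedding is pushed towards being useless for confounder
#' prediction. The adversary uses a private RNG stream: with
#' `lambda_adv = 0` the XVAE trajectory is identical to [train_xvae()] at
#' the same seed.
#'
#' `variant = "multiclass"` (default) uses one adversary over the joint
#' class labels of all confounders; `"sequential"` trains one adversary
#' per confounder and sums the penalty terms.
#'
#' @param model A built [build_xvae()] model (unconditioned).
#' @param data Dataset object as in [train_xvae()].
#' @param confounders Vector or list of discrete confounder vectors.
#' @param adv An [adversary_config()].
#' @param variant `"multiclass"` or `"sequential"`.
#' @return Trained model; `$adversaries` holds the final adversary
#'   network(s).
#' @export
train_adv_xvae <- function(model, data, confounders,
                           adv = adversary_config(),
                           variant = c("multiclass", "sequential")) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "xvae"))
  v <- dataset_views(data)
  if (!is.list(confounders)) confounders <- list(confounders)
  each <- lapply(confounders, confounder_classes)  # validates discreteness
  cls <- if (variant == "multiclass") {
    list(confounder_classes(interaction(as.data.frame(confounders), drop = TRUE)))
  } else {
    each
  }
  d <- model$cfg$latent_dim
  hook_env <- new.env(parent = emptyenv())
  hook_env$rng <- with_seed(derive_seed(model$cfg$seed, 31L), get_rng_state())
  hook_env$nets <- NULL
  hook_env$states <- NULL

  hook <- function(m, epoch, tr_idx) {
    if (is.null(hook_env$nets)) {
      hook_env$nets <- lapply(cls, function(cl) adversary_build(d, cl$K, adv$hidden))
      hook_env$states <- lapply(hook_env$nets, adam_init)
    }
    tr <- tr_idx
    ## adversary sees a sampled embedding (not the deterministic means):
    ## the posterior noise stops it from memorising individual samples of
    ## an unpredictable confounder
    fwf <- xvae_fwd(m, v$X1, v$X2, cond_rows(m, seq_len(nrow(v$X1))),
                    eps = matrix(stats::rnorm(nrow(v$X1) * d), nrow(v$X1), d))
    Zfull <- fwf$z
    for (rep in seq_len(adv$steps_per_alternation)) {
      perm <- sample(tr)
      starts <- seq(1L, length(perm), by = m$cfg$batch_size)
      for (ci in seq_along(cls)) {
        net <- hook_env$nets[[ci]]
        st <- hook_env$states[[ci]]
        y_all <- cls[[ci]]$y
        for (s in starts) {
          idx <- perm[s:min(s + m$cfg$batch_size - 1L, length(perm))]
          if (length(idx) < 2L) next
          Z <- Zfull[idx, , drop = FALSE]
          fw <- adversary_fwd(net, Z)
          bw <- adversary_bwd(net, Z, fw, y_all[idx])
          upd <- adam_step(net, bw$grads, st, lr = adv$learning_rate)
          net <- upd$params
          st <- upd$state
        }
        hook_env$nets[[ci]] <- net
        hook_env$states[[ci]] <- st
      }
    }
    m
  }

  penalty <- function(z, idx) {
    if (is.null(hook_env$nets)) return(list(value = 0, grad = NULL))
    val <- 0
    grad <- matrix(0, nrow(z), ncol(z))
    for (ci in seq_along(cls)) {
      fw <- adversary_fwd(hook_env$nets[[ci]], z)
      ce <- adversary_ce(fw, cls[[ci]]$y[idx])
      ## the bonus for confusing the adversary is capped at chance level
      ## (CE = log K): pushing the frozen adversary beyond chance into
      ## anti-prediction would destroy unrelated latent structure
      chance <- log(cls[[ci]]$K)
      if (ce < chance) {
        bw <- adversary_bwd(hook_env$nets[[ci]], z, fw, cls[[ci]]$y[idx])
        val <- val - adv$lambda_adv * ce
        grad <- grad - adv$lambda_adv * bw$dZ
      } else {
        val <- val - adv$lambda_adv * chance
      }
    }
    list(value = val, grad = grad)
  }

  model <- train_core(model, v$X1, v$X2,
                      penalty = penalty,
                      penalty_from = adv$pretrain_epochs + 1L,
                      hook = hook,
                      hook_from = max(adv$pretrain_epochs, 1L),
                      hook_env = hook_env)
  model$adversaries <- hook_env$nets
  model
}

#' Specification of the confounder-association penalty (cr-XVAE)
#'
#' @param method Association measure between each latent dimension and the
#'   confounder: `"abs_corr"` (mean absolute Pearson correlation),
#'   `"sq_corr"` (mean squared correlation; the best-performing variant),
#'   `"mi_histogram"` (soft-binned differentiable histogram mutual
#'   information), or `"mi_kde"` (Gaussian-KDE plug-in mutual
#'   information).
#' @param lambda_cr Penalty weight (>= 0) applied when composed into the
#'   training loss.
#' @param bins Number of soft bins for `"mi_histogram"`.
#' @param bandwidth Optional KDE bandwidth for `"mi_kde"`; default Scott's
#'   rule `sd(z) * n^(-1/5)`.
#' @return List of class `cr_penalty_spec`.
#' @export
cr_penalty_spec <- function(method = c("sq_corr", "abs_corr",
                                       "mi_histogram", "mi_kde"),
                            lambda_cr = 1, bins = 10L, bandwidth = NULL) {
  method <- match.arg(method)
  if (lambda_cr < 0) stopf("lambda_cr must be >= 0")
  structure(list(method = method, lambda_cr = lambda_cr,
                 bins = as.integer(bins), bandwidth = bandwidth),
            class = "cr_penalty_spec")
}

## Pearson r of one latent dim against c, with gradient w.r.t. the dim.
pearson_with_grad <- function(x, cc_std, sc_ok, n) {
  xc <- x - mean(x)
  sx <- sqrt(mean(xc^2))
  if (sx == 0 || !sc_ok) return(list(r = 0, dr = numeric(n)))
  xh <- xc / sx
  r <- mean(xh * cc_std)
  dr <- (cc_std - r * xh) / (n * sx)
  list(r = r, dr = dr)
}

#' Association penalty between latent dimensions and a confounder
#'
#' Mean over latent dimensions of the chosen association measure between
#' each dimension and the confounder (see [cr_penalty_spec()]).
#' Zero-variance dimensions (or a constant confounder) contribute 0.
#' Mutual-information methods require a discrete confounder.
#'
#' @param z n x d latent matrix.
#' @param c Confounder vector of length n.
#' @param spec A [cr_penalty_spec()].
#' @return Non-negative scalar (unweighted; multiply by `spec$lambda_cr`
#'   to compose into a loss).
#' @export
cr_penalty <- function(z, c, spec = cr_penalty_spec()) {
  cr_penalty_impl(as.matrix(z), c, spec, want_grad = FALSE)$value
}

cr_penalty_impl <- function(z, c, spec, want_grad = TRUE) {
  n <- nrow(z)
  d <- ncol(z)
  if (n < 3L) stopf("cr_penalty: need n >= 3")
  if (length(c) != n) stopf("cr_penalty: length(c) != nrow(z)")
  val <- 0
  G <- if (want_grad) matrix(0, n, d) else NULL
  if (spec$method %in% c("abs_corr", "sq_corr")) {
    cnum <- if (is.numeric(c)) c else as.numeric(factor(c))
    ccn <- cnum - mean(cnum)
    sc <- sqrt(mean(ccn^2))
    sc_ok <- sc > 0
    cc_std <- if (sc_ok) ccn / sc else ccn
    for (j in seq_len(d)) {
      pg <- pearson_with_grad(z[, j], cc_std, sc_ok, n)
      if (spec$method == "abs_corr") {
        val <- val + abs(pg$r)
        if (want_grad) G[, j] <- sign(pg$r) * pg$dr
      } else {
        val <- val + pg$r^2
        if (want_grad) G[, j] <- 2 * pg$r * pg$dr
      }
    }
  } else {
    cl <- confounder_classes(c)
    for (j in seq_len(d)) {
      mi <- if (spec$method == "mi_histogram") {
        mi_hist_1d(z[, j], cl, bins = spec$bins, want_grad = want_grad)
      } else {
        mi_kde_1d(z[, j], cl, bandwidth = spec$bandwidth, want_grad = want_grad)
      }
      val <- val + mi$value
      if (want_grad) G[, j] <- mi$grad
    }
  }
  if (want_grad) G <- G / d
  list(value = max(val / d, 0), grad = G)
}

## Differentiable soft-histogram MI between x and discrete classes.
## Bin edges/centres are treated as constants of the current batch.
mi_hist_1d <- function(x, cl, bins = 10L, want_grad = TRUE) {
  n <- length(x)
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    return(list(value = 0, grad = numeric(n)))
  }
  centers <- seq(rng[1], rng[2], length.out = bins)
  delta <- (rng[2] - rng[1]) / bins / 2
  U <- exp(-outer(x, centers, "-")^2 / (2 * delta^2))
  rho <- U / rowSums(U)
  Y <- diag(cl$K)[cl$y, , drop = FALSE]
  Pkb <- crossprod(Y, rho) / n
  Pb <- colSums(Pkb)
  pk <- rowSums(Pkb)
  eps <- 1e-12
  A <- log((Pkb + eps) / (outer(pk, Pb) + eps))
  value <- sum(Pkb * A)
  grad <- NULL
  if (want_grad) {
    T_ib <- outer(x, centers, function(a, b) (b - a)) / delta^2
    Ai <- A[cl$y, , drop = FALSE]
    tau <- rowSums(rho * T_ib)
    grad <- rowSums(Ai * rho * (T_ib - tau)) / n
  }
  list(value = max(value, 0), grad = grad)
}

## KDE plug-in MI for discrete classes: MI = H(x) - sum_k pi_k H(x | k),
## entropies by Gaussian-KDE plug-in; one shared bandwidth (Scott's rule
## on the full sample) held fixed for differentiation.
mi_kde_1d <- function(x, cl, bandwidth = NULL, want_grad = TRUE) {
  n <- length(x)
  h <- bandwidth %||% (stats::sd(x) * n^(-1 / 5))
  if (!is.finite(h) || h <= 0) return(list(value = 0, grad = numeric(n)))
  ent <- function(xs) {
    m <- length(xs)
    D <- outer(xs, xs, "-")
    Phi <- exp(-D^2 / (2 * h^2)) / (h * sqrt(2 * pi))
    f <- rowMeans(Phi)
    W <- Phi * D / h^2
    gG <- (-rowSums(W) / f + colSums(W / f)) / m
    list(H = -mean(log(f)), gH = -gG / m)
  }
  full <- ent(x)
  value <- full$H
  grad <- if (want_grad) full$gH else NULL
  for (k in seq_len(cl$K)) {
    idx <- which(cl$y == k)
    if (length(idx) < 2L) next
    ek <- ent(x[idx])
    w <- length(idx) / n
    value <- value - w * ek$H
    if (want_grad) grad[idx] <- grad[idx] - w * ek$gH
  }
  list(value = max(value, 0), grad = grad)
}

#' Train a correlation/MI-regularised XVAE (cr-XVAE)
#'
#' The XVAE loss is augmented per batch by `lambda_cr` times the
#' association penalty [cr_penalty()] between the sampled latent
#' dimensions and each confounder (mean over confounders), discouraging
#' the latent space from encoding the confounder.
#'
#' @param model A built [build_xvae()] model.
#' @param data Dataset object as in [train_xvae()].
#' @param confounders Vector or list of confounder vectors.
#' @param spec A [cr_penalty_spec()].
#' @return Trained model with loss history (`train_penalty` column logs
#'   the weighted penalty).
#' @export
train_cr_xvae <- function(model, data, confounders,
                          spec = cr_penalty_spec()) {
  stopifnot(inherits(model, "xvae"))
  v <- dataset_views(data)
  if (!is.list(confounders)) confounders <- list(confounders)
  penalty <- function(z, idx) {
    val <- 0
    grad <- matrix(0, nrow(z), ncol(z))
    for (cf in confounders) {
      part <- cr_penalty_impl(z, cf[idx], spec, want_grad = TRUE)
      val <- val + part$value
      grad <- grad + part$grad
    }
    nconf <- length(confounders)
    list(value = spec$lambda_cr * val / nconf,
         grad = spec$lambda_cr * grad / nconf)
  }
  train_core(model, v$X1, v$X2, penalty = penalty)
}

#' Criterion for removing confounded latent features (XVAE+FS)
#'
#' @param method `"pvalue"` (remove dimensions whose Pearson correlation
#'   with a confounder is significant at `threshold`) or `"abs_corr"`
#'   (remove dimensions with `|r| > threshold`; 0.3 = weak, 0.5 = strong
#'   correlation, the latter being the best-performing cutoff).
#' @param threshold Cutoff in (0, 1); defaults 0.05 for `"pvalue"`, 0.5
#'   for `"abs_corr"`.
#' @return List of class `fs_criterion`.
#' @export
fs_criterion <- function(method = c("pvalue", "abs_corr"), threshold = NULL) {
  method <- match.arg(method)
  threshold <- threshold %||% if (method == "pvalue") 0.05 else 0.5
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  structure(list(method = method, threshold = threshold),
            class = "fs_criterion")
}

#' Post-hoc selection of unconfounded latent dimensions
#'
#' Computes the Pearson correlation between each latent posterior-mean
#' dimension and each confounder, and removes a dimension if it violates
#' the criterion for any confounder. Applied to posterior means so the
#' selection is deterministic and shared across all consensus draws. If
#' every dimension would be removed, the single dimension with the
#' smallest maximum absolute correlation is retained with a warning.
#'
#' @param post_mean n x d matrix of latent posterior means.
#' @param confounders Vector or list of confounder vectors (non-numeric
#'   ones are coerced to their integer codes).
#' @param crit An [fs_criterion()].
#' @return Sorted integer vector of retained dimension indices.
#' @export
filter_latent_features <- function(post_mean, confounders,
                                   crit = fs_criterion("abs_corr", 0.5)) {
  post_mean <- as.matrix(post_mean)
  n <- nrow(post_mean)
  if (n < 3L) stopf("filter_latent_features: need n >= 3")
  if (!is.list(confounders)) confounders <- list(confounders)
  d <- ncol(post_mean)
  maxabs <- numeric(d)
  remove <- logical(d)
  for (cf in confounders) {
    cnum <- if (is.numeric(cf)) cf else as.numeric(factor(cf))
    for (j in seq_len(d)) {
      zj <- post_mean[, j]
      if (stats::sd(zj) == 0 || stats::sd(cnum) == 0) next
      ct <- stats::cor.test(zj, cnum)
      r <- unname(ct$estimate)
      maxabs[j] <- max(maxabs[j], abs(r))
      bad <- if (crit$method == "pvalue") ct$p.value < crit$threshold
      else abs(r) > crit$threshold
      if (bad) remove[j] <- TRUE
    }
  }
  keep <- which(!remove)
  if (length(keep) == 0L) {
    keep <- which.min(maxabs)
    warning("all latent dimensions violated the criterion; retaining the least correlated one")
  }
  sort(keep)
}

#' Linear-regression residualisation plus PCA baseline (LR+PCA)
#'
#' The conventional pipeline: ordinary least squares of every feature on
#' the confounder covariates (numeric as given, categorical one-hot with
#' the first level dropped, plus intercept), residuals taken as adjusted
#' features, both views concatenated, PCA applied, and KMeans (10 random
#' initialisations, best inertia kept) run on the leading principal
#' components.
#'
#' @param X1,X2 View matrices (samples x features).
#' @param confounders Vector or list of confounder vectors.
#' @param n_pcs Number of principal components (default 50; capped at the
#'   rank of the residual matrix).
#' @param k Number of clusters.
#' @param seed Integer seed for KMeans.
#' @param kmeans_inits Number of random KMeans initialisations.
#' @return List with `labels` (integer cluster assignment), `embedding`
#'   (the n x n_pcs score matrix) and `residuals` (the concatenated
#'   confounder-adjusted feature matrix).
#' @export
lr_pca_baseline <- function(X1, X2, confounders, n_pcs = 50L, k, seed = 1L,
                            kmeans_inits = 10L) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  n <- nrow(X1)
  if (!is.list(confounders)) confounders <- list(confounders)
  cols <- lapply(confounders, function(cf) {
    if (is.numeric(cf)) matrix(cf, ncol = 1)
    else {
      f <- factor(cf)
      diag(nlevels(f))[as.integer(f), -1, drop = FALSE]
    }
  })
  D <- cbind(rep(1, n), do.call(cbind, cols))
  if (n <= ncol(D)) stopf("need n > number of regression covariates")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("dropping collinear confounder columns from the design")
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    qrD <- qr(D)
  }
  R <- cbind(qr.resid(qrD, X1), qr.resid(qrD, X2))
  pc <- stats::prcomp(R, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_pcs, ncol(pc$x)))
  emb <- pc$x[, keep, drop = FALSE]
  labels <- with_seed(seed, seeded_kmeans(emb, k, kmeans_inits))
  list(labels = labels, embedding = emb, residuals = R)
}
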