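## Independent brute-force oracles used to verify the package's metric and
## consensus implementations. Deliberately written with explicit loops and
## the textbook formulas, sharing no code with R/.

bf_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  ri_pairs <- s11
  exp_idx <- (s11 + s10) * (s11 + s01) / (s11 + s10 + s01 + s00)
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(if (ri_pairs == exp_idx) 1 else 0)
  (ri_pairs - exp_idx) / (max_idx - exp_idx)
}

bf_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a)
  ub <- unique(b)
  mi <- 0
  for (x in ua) {
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  ha <- 0
  for (x in ua) { px <- sum(a == x) / n; ha <- ha - px * log(px) }
  hb <- 0
  for (y in ub) { py <- sum(b == y) / n; hb <- hb - py * log(py) }
  if (ha + hb == 0) return(1)
  mi / ((ha + hb) / 2)
}

bf_dispersion <- function(A) {
  n <- nrow(A)
  tot <- 0
  for (i in 1:n) for (j in 1:n) tot <- tot + (A[i, j] - 0.5)^2 * 4
  tot / n^2
}

bf_coassign <- function(labels) {
  n <- length(labels)
  A <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (labels[i] == labels[j]) A[i, j] <- 1
  A
}

bf_consensus <- function(label_list) {
  acc <- bf_coassign(label_list[[1]]) * 0
  for (lab in label_list) acc <- acc + bf_coassign(lab)
  acc / length(label_list)
}

bf_relative_error <- function(x, xr) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(x))) {
    num <- num + sum((x[i, ] - xr[i, ])^2)
    den <- den + sum(x[i, ]^2)
  }
  sqrt(num) / sqrt(den)
}

bf_relative_error_combined <- function(x1, x1r, x2, x2r) {
  num <- den <- 0
  for (v in list(list(x1, x1r), list(x2, x2r))) {
    nv <- dv <- 0
    for (i in seq_len(nrow(v[[1]]))) {
      nv <- nv + sum((v[[1]][i, ] - v[[2]][i, ])^2)
      dv <- dv + sum(v[[1]][i, ]^2)
    }
    num <- num + sqrt(nv)
    den <- den + sqrt(dv)
  }
  num / den
}

bf_mmd <- function(A, B, scales) {
  gk <- function(x, y, s) exp(-sum((x - y)^2) / (2 * s^2))
  val <- 0
  for (s in scales) {
    saa <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
      saa <- saa + gk(A[i, ], A[j, ], s)
    sbb <- 0
    for (i in seq_len(nrow(B))) for (j in seq_len(nrow(B)))
      sbb <- sbb + gk(B[i, ], B[j, ], s)
    sab <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      sab <- sab + gk(A[i, ], B[j, ], s)
    val <- val + saa / nrow(A)^2 + sbb / nrow(B)^2 - 2 * sab / (nrow(A) * nrow(B))
  }
  val / length(scales)
}

## a vector with exact sample Pearson correlation r against cf
make_correlated <- function(cf, r, seed) {
  set.seed(seed)
  n <- length(cf)
  e <- rnorm(n)
  e <- residuals(lm(e ~ cf))
  ch <- (cf - mean(cf)) / sqrt(mean((cf - mean(cf))^2))
  eh <- (e - mean(e)) / sqrt(mean((e - mean(e))^2))
  r * ch + sqrt(1 - r^2) * eh
}

## shared small-scale training fixtures
tiny_cfg <- function(seed = 1L, epochs = 8L) {
  xvae_config(view_hidden = 16L, fused_hidden = 16L, latent_dim = 8L,
              epochs = epochs, batch_size = 64L, seed = seed)
}

tiny_data <- function(seed = 2L, n = 200L, p = 20L, q = 20L, k = 4L,
                      signal = 1) {
  d <- generate_paired_omics(n, p, q, k, signal = signal, seed = seed)
  d$view1 <- rescale_unit(d$view1)
  d$view2 <- rescale_unit(d$view2)
  d
}

## desk-scale fixture of the acceptance criteria (memoised per session)
desk_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_paired_omics(600, 50, 50, 6, signal = 1.5, seed = 1)
      d$view1 <- rescale_unit(d$view1)
      d$view2 <- rescale_unit(d$view2)
      eff <- categorical_effect(600, 50, 50, seed = 101)
      cache <<- list(base = d, eff = eff, conf = apply_effects(d, eff))
    }
    cache
  }
})

desk_cfg <- function(seed) {
  xvae_config(view_hidden = 128L, fused_hidden = 128L, latent_dim = 16L,
              epochs = 50L, learning_rate = 5e-3,
              early_stop_patience = 20L, seed = seed)
}
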