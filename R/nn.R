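## Minimal dense-network machinery (He init, ReLU, Adam). The models here
## are small (hundreds of units), so plain R matrix algebra is fast enough
## and keeps the package dependency-free.

init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

dense_fwd <- function(layer, X) {
  sweep(X %*% layer$W, 2L, layer$b, "+")
}

relu <- function(X) {
  X[X < 0] <- 0
  X
}

## gradient of a dense layer: delta = dL/d(pre-activation output)
## returns grads and dL/dX
dense_bwd <- function(layer, X, delta) {
  list(dW = crossprod(X, delta), db = colSums(delta),
       dX = tcrossprod(delta, layer$W))
}

## Adam over a flat named list of parameter lists {W, b}
adam_init <- function(params) {
  zero_like <- function(x) lapply(x, function(p) p * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (pn in names(params[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (is.null(g)) next
      state$m[[nm]][[pn]] <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      state$v[[nm]][[pn]] <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[pn]] / bc1
      vhat <- state$v[[nm]][[pn]] / bc2
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
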