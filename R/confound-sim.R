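#' Draw a discrete numeric confounder
#'
#' Uniform iid draws over the integer levels `0..n_levels-1` (default six
#' levels, 0 to 5), mimicking e.g. a binned age variable. Such a
#' confounder induces a six-class confounder partition of the samples.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param n_levels Number of discrete levels (default 6).
#' @return Integer vector of length `n` with values in `0:(n_levels-1)`.
#' @export
draw_numeric_confounder <- function(n, seed = 1, n_levels = 6L) {
  if (n < 1) stopf("n must be >= 1")
  with_seed(seed, sample(0:(n_levels - 1L), n, replace = TRUE))
}

new_confounding_effect <- function(kind, E1, E2, label, w1 = NULL, w2 = NULL,
                                   extras = list()) {
  structure(
    c(list(kind = kind, E1 = E1, E2 = E2,
           confounder_label = as.integer(label),
           feature_weight1 = w1, feature_weight2 = w2), extras),
    class = "confounding_effect"
  )
}

#' @export
print.confounding_effect <- function(x, ...) {
  cat(sprintf("confounding_effect: kind=%s, E1 %dx%d, E2 %dx%d\n",
              x$kind, nrow(x$E1), ncol(x$E1), nrow(x$E2), ncol(x$E2)))
  invisible(x)
}

#' Additive confounding effect simulators
#'
#' Build ground-truth additive effect matrices `E1` (n x p), `E2` (n x q)
#' for a paired dataset whose features were first rescaled to `[0, 1]`:
#'
#' * `linear_effect()`: `E_v = (c + 5) %o% w_v` with per-feature weights
#'   `w1 ~ U(0, 0.1)` and `w2 ~ U(0, 0.2)`, so that the total linear
#'   effect on view 1 spans 0 to 1 — the same scale as the data. The
#'   shift by 5 makes the effect act on every sample.
#' * `square_effect()`: `E_v = c^2 %o% w_v`, `w1, w2 ~ U(0, 0.04)`
#'   (so the maximum effect `25 * 0.04 = 1` again matches the data scale),
#'   emulating quadratic confounders such as BMI.
#' * `categorical_effect()`: samples are randomly assigned (near-balanced)
#'   to `n_classes` classes; each class has a shift direction per view
#'   drawn from `U(0, 1)` per feature, and each sample a shift magnitude
#'   `w ~ U(0, 1)`, giving `E_v = diag(w) %*% C_v` — a batch-effect-like
#'   displacement of whole classes.
#'
#' Each returned `confounding_effect` carries `confounder_label`, the
#' partition against which deconfounding is later evaluated (`c` itself
#' for linear/square, the class assignment for categorical).
#'
#' @param n,p,q Dataset dimensions (samples, view-1 features, view-2
#'   features).
#' @param c Integer confounder vector from [draw_numeric_confounder()].
#' @param w1_hi,w2_hi,w_hi Upper bounds of the uniform weight
#'   distributions.
#' @param seed Integer seed for the weight draws.
#' @param w1,w2 Optional fixed weight vectors overriding the random draw
#'   (used in tests and for reproducing a stored simulation).
#' @param n_classes Number of confounder classes for the categorical
#'   effect.
#' @return A `confounding_effect` object (for `categorical_effect` it
#'   additionally carries `class_of`, `shift1`, `shift2`,
#'   `sample_weight`).
#' @export
linear_effect <- function(n, p, q, c, w1_hi = 0.1, w2_hi = 0.2, seed = 1,
                          w1 = NULL, w2 = NULL) {
  if (length(c) != n) stopf("confounder length %d != n = %d", length(c), n)
  with_seed(seed, {
    w1 <- w1 %||% stats::runif(p, 0, w1_hi)
    w2 <- w2 %||% stats::runif(q, 0, w2_hi)
    new_confounding_effect("linear",
                           E1 = outer(c + 5, w1), E2 = outer(c + 5, w2),
                           label = c, w1 = w1, w2 = w2)
  })
}

#' @rdname linear_effect
#' @export
square_effect <- function(n, p, q, c, w_hi = 0.04, seed = 1,
                          w1 = NULL, w2 = NULL) {
  if (length(c) != n) stopf("confounder length %d != n = %d", length(c), n)
  with_seed(seed, {
    w1 <- w1 %||% stats::runif(p, 0, w_hi)
    w2 <- w2 %||% stats::runif(q, 0, w_hi)
    new_confounding_effect("square",
                           E1 = outer(c^2, w1), E2 = outer(c^2, w2),
                           label = c, w1 = w1, w2 = w2)
  })
}

#' @rdname linear_effect
#' @export
categorical_effect <- function(n, p, q, n_classes = 6L, seed = 1) {
  if (n < n_classes) stopf("need n >= n_classes (%d < %d)", n, n_classes)
  with_seed(seed, {
    class_of <- sample(rep_len(seq_len(n_classes), n))
    shift1 <- matrix(stats::runif(n_classes * p), n_classes, p)
    shift2 <- matrix(stats::runif(n_classes * q), n_classes, q)
    w <- stats::runif(n)
    new_confounding_effect("categorical",
                           E1 = w * shift1[class_of, , drop = FALSE],
                           E2 = w * shift2[class_of, , drop = FALSE],
                           label = class_of,
                           extras = list(class_of = as.integer(class_of),
                                         shift1 = shift1, shift2 = shift2,
                                         sample_weight = w))
  })
}

#' @rdname linear_effect
#' @param seeds Integer vector of three independent seeds (linear, square,
#'   categorical). The three effects use mutually independent confounder
#'   variables, so each carries its own evaluation label.
#' @export
mixed_effect <- function(n, p, q, seeds = c(1L, 2L, 3L), n_classes = 6L) {
  stopifnot(length(seeds) == 3L)
  c_lin <- draw_numeric_confounder(n, seed = derive_seed(seeds[1], 11L))
  c_sq <- draw_numeric_confounder(n, seed = derive_seed(seeds[2], 13L))
  list(
    linear = linear_effect(n, p, q, c_lin, seed = seeds[1]),
    square = square_effect(n, p, q, c_sq, seed = seeds[2]),
    categorical = categorical_effect(n, p, q, n_classes = n_classes, seed = seeds[3])
  )
}

#' Apply additive confounding effects to a paired dataset
#'
#' The effects are purely additive and no clipping is applied, so
#' `confounded == base + sum(E)` holds exactly; the base views must
#' already be rescaled to `[0, 1]` (effect scales assume it).
#'
#' @param base A `paired_omics` object (from [generate_paired_omics()]) whose views lie in `[0, 1]`.
#' @param effects A single `confounding_effect` or a list of them.
#' @return Object of class `confounded_omics`: the base dataset plus
#'   matrices `confounded1`, `confounded2` and the list of `effects`.
#' @seealso [linear_effect()], [generate_paired_omics()]
#' @export
apply_effects <- function(base, effects) {
  stopifnot(inherits(base, "paired_omics"))
  if (inherits(effects, "confounding_effect")) effects <- list(effects)
  if (min(base$view1, base$view2) < 0 || max(base$view1, base$view2) > 1) {
    stopf("base views must be unit-rescaled before applying effects (see rescale_unit)")
  }
  X1 <- base$view1
  X2 <- base$view2
  for (e in effects) {
    stopifnot(inherits(e, "confounding_effect"))
    if (!all(dim(e$E1) == dim(X1)) || !all(dim(e$E2) == dim(X2))) {
      stopf("effect '%s' has mismatched shape", e$kind)
    }
    X1 <- X1 + e$E1
    X2 <- X2 + e$E2
  }
  structure(
    list(base = base, confounded1 = X1, confounded2 = X2, effects = effects),
    class = "confounded_omics"
  )
}

#' @export
print.confounded_omics <- function(x, ...) {
  cat(sprintf("confounded_omics: %d samples, effects: %s\n",
              nrow(x$confounded1),
              paste(vapply(x$effects, `[[`, "", "kind"), collapse = " + ")))
  invisible(x)
}

#' Confounder evaluation labels of a confounded dataset
#'
#' @param data A `confounded_omics` object.
#' @return Named list of integer label vectors, one per effect.
#' @export
confounder_labels <- function(data) {
  stopifnot(inherits(data, "confounded_omics"))
  labs <- lapply(data$effects, `[[`, "confounder_label")
  names(labs) <- vapply(data$effects, `[[`, "", "kind")
  labs
}
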