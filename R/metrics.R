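#' Relative reconstruction error
#'
#' `relative_error_view()` is the ratio of the Frobenius norm of the
#' residual to the Frobenius norm of the input,
#' `sqrt(sum(||x_i - x_i'||^2)) / sqrt(sum(||x_i||^2))`.
#' `relative_error_combined()` extends it to two views as the sum of the
#' per-view numerators over the sum of the per-view denominators (a
#' mediant: it always lies between the two per-view errors, and equals
#' them when they agree).
#'
#' @param x,x1,x2 Input matrices.
#' @param xr,x1r,x2r Reconstructions of matching shape.
#' @return Non-negative scalar; 0 for a perfect reconstruction, 1 when
#'   the reconstruction is identically zero.
#' @export
relative_error_view <- function(x, xr) {
  x <- as.matrix(x)
  xr <- as.matrix(xr)
  if (!all(dim(x) == dim(xr))) stopf("relative_error_view: shape mismatch")
  den <- sqrt(sum(x^2))
  if (den == 0) stopf("relative_error_view: input is all zero")
  sqrt(sum((x - xr)^2)) / den
}

#' @rdname relative_error_view
#' @export
relative_error_combined <- function(x1, x1r, x2, x2r) {
  num <- sqrt(sum((as.matrix(x1) - as.matrix(x1r))^2)) +
    sqrt(sum((as.matrix(x2) - as.matrix(x2r))^2))
  den <- sqrt(sum(as.matrix(x1)^2)) + sqrt(sum(as.matrix(x2)^2))
  if (den == 0) stopf("relative_error_combined: zero denominator")
  num / den
}

#' Dispersion score of a consensus matrix
#'
#' `4 * mean((A_bar - 0.5)^2)`, over all entries including the diagonal.
#' Ranges from 0 (all entries 0.5: no consensus) to 1 (every entry 0 or
#' 1: perfectly stable clustering across draws).
#'
#' @param cm A `consensus_matrix` or a bare numeric matrix with entries
#'   in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
dispersion <- function(cm) {
  A <- if (inherits(cm, "consensus_matrix")) cm$matrix else as.matrix(cm)
  if (min(A) < 0 || max(A) > 1) stopf("dispersion: entries must lie in [0, 1]")
  sum((A - 0.5)^2 * 4) / length(A)
}

#' Adjusted Rand index and normalised mutual information
#'
#' `ari()` is the pair-counting Rand index adjusted for chance (1 for
#' identical partitions up to relabelling, about 0 for independent ones,
#' may be negative). `nmi()` is mutual information normalised by the
#' arithmetic mean of the two entropies, in `[0, 1]`. Both are symmetric
#' in their arguments.
#'
#' @param a,b Label vectors of equal length (any type coercible to
#'   factor).
#' @return Scalar.
#' @export
ari <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  if (n < 2) stopf("ari: need at least two samples")
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (mx - expected)
}

#' @rdname ari
#' @export
nmi <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  if (n < 2) stopf("nmi: need at least two samples")
  pij <- ct / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  val <- mi / ((ha + hb) / 2)
  min(max(val, 0), 1)
}

contingency <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  table(factor(a), factor(b))
}

#' Evaluate a model's clustering against truth and confounders
#'
#' Convenience wrapper assembling the evaluation report: per-view and
#' combined relative reconstruction errors, consensus dispersion, and
#' ARI/NMI of the derived clustering against the true labels and each
#' confounder label.
#'
#' @param labels Derived cluster labels.
#' @param true_labels Ground-truth labels.
#' @param confounder_labels Named list of confounder label vectors (may
#'   be empty).
#' @param cm Optional consensus matrix for the dispersion score.
#' @param x1,x1r,x2,x2r Optional inputs and reconstructions for the
#'   relative errors.
#' @return List of class `eval_report`.
#' @export
eval_report <- function(labels, true_labels, confounder_labels = list(),
                        cm = NULL, x1 = NULL, x1r = NULL, x2 = NULL,
                        x2r = NULL) {
  rep <- list(
    ari_true = ari(labels, true_labels),
    nmi_true = nmi(labels, true_labels),
    ari_confounder = lapply(confounder_labels, function(cl) ari(labels, cl)),
    nmi_confounder = lapply(confounder_labels, function(cl) nmi(labels, cl)),
    dispersion = if (!is.null(cm)) dispersion(cm) else NA_real_,
    re_view1 = if (!is.null(x1)) relative_error_view(x1, x1r) else NA_real_,
    re_view2 = if (!is.null(x2)) relative_error_view(x2, x2r) else NA_real_,
    re_combined = if (!is.null(x1) && !is.null(x2))
      relative_error_combined(x1, x1r, x2, x2r) else NA_real_
  )
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: RE=%.3f, dispersion=%.3f, ARI(true)=%.3f",
              x$re_combined, x$dispersion, x$ari_true))
  if (length(x$ari_confounder)) {
    cat(", ARI(confounder): ",
        paste(sprintf("%s=%.3f", names(x$ari_confounder),
                      unlist(x$ari_confounder)), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}
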