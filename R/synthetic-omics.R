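#' Generate a paired two-view omics dataset with known cluster structure
#'
#' Simulates the statistical shape of a paired expression/methylation
#' dataset: `n` samples shared between two views, with `k` near-balanced
#' ground-truth clusters. View 1 is continuous and expression-like
#' (Gaussian noise around cluster-specific mean-shift vectors scaled by
#' `signal`); view 2 is methylation-like, drawn from a bimodal mixture of
#' Beta(2, 10) and Beta(10, 2) whose mode membership is cluster-biased
#' through `signal`.
#'
#' Draw order (documented so results are reproducible across versions):
#' cluster labels, view-1 cluster means, view-1 noise, view-2 cluster
#' logits, view-2 mode indicators, view-2 low-mode betas, view-2 high-mode
#' betas.
#'
#' @param n,p,q Number of samples and of features in view 1 / view 2.
#' @param k Number of ground-truth clusters (`2 <= k <= n`).
#' @param signal Non-negative effect size separating the clusters; 0 means
#'   the labels are independent of the data.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `paired_omics`: list with numeric matrices
#'   `view1` (n x p), `view2` (n x q) carrying sample/feature dimnames,
#'   integer `true_labels` in `1:k`, and `seed`.
#' @examples
#' d <- generate_paired_omics(n = 60, p = 10, q = 10, k = 3, signal = 2, seed = 1)
#' table(d$true_labels)
#' @export
generate_paired_omics <- function(n, p, q, k, signal = 1, seed = 1) {
  if (n < 1 || p < 1 || q < 1) stopf("n, p, q must be positive (got n=%s, p=%s, q=%s)", n, p, q)
  if (k < 2 || k > n) stopf("need n >= k >= 2 (got n=%s, k=%s)", n, k)
  if (signal < 0) stopf("signal must be >= 0")
  with_seed(seed, {
    labels <- sample(rep_len(seq_len(k), n))
    mu1 <- matrix(stats::rnorm(k * p), k, p)
    view1 <- signal * mu1[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * p), n, p)
    eta2 <- matrix(stats::rnorm(k * q), k, q)
    pr_hi <- stats::plogis(signal * eta2)[labels, , drop = FALSE]
    hi <- matrix(stats::rbinom(n * q, 1L, as.vector(pr_hi)), n, q)
    lo_draw <- matrix(stats::rbeta(n * q, 2, 10), n, q)
    hi_draw <- matrix(stats::rbeta(n * q, 10, 2), n, q)
    view2 <- ifelse(hi == 1L, hi_draw, lo_draw)
    sample_ids <- sprintf("S%04d", seq_len(n))
    dimnames(view1) <- list(sample_ids, sprintf("ge%04d", seq_len(p)))
    dimnames(view2) <- list(sample_ids, sprintf("me%04d", seq_len(q)))
    structure(
      list(view1 = view1, view2 = view2,
           true_labels = as.integer(labels), seed = as.integer(seed)),
      class = "paired_omics"
    )
  })
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("paired_omics: %d samples, view1 %d features, view2 %d features, %d clusters\n",
              nrow(x$view1), ncol(x$view1), ncol(x$view2),
              length(unique(x$true_labels))))
  invisible(x)
}

#' Rescale each feature to the unit interval
#'
#' Maps every column by `(x - min) / (max - min)` so that non-constant
#' features span exactly `[0, 1]`. Constant columns map to all zeros (the
#' affine map is undefined there; zero keeps the output range invariant).
#' Applied to raw features before any confounding effect is added, so that
#' effect and feature share the same scale.
#'
#' @param X Numeric matrix (samples x features), all values finite.
#' @return Matrix of the same shape and dimnames with columns in `[0, 1]`.
#' @export
rescale_unit <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("rescale_unit: X must be finite")
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  out <- sweep(X, 2L, lo, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  out
}

#' Keep the features with largest variance
#'
#' Standard top-variance filtering used to reduce omics matrices to a
#' tractable feature set. Returns the `m` columns with the largest sample
#' variance, preserving their original relative order; ties are broken by
#' original column index (first wins).
#'
#' @param X Numeric matrix (samples x features).
#' @param m Number of features to keep, `m <= ncol(X)`.
#' @return Matrix with `m` columns.
#' @export
variance_filter <- function(X, m) {
  X <- as.matrix(X)
  if (m > ncol(X)) stopf("variance_filter: m (%d) exceeds feature count (%d)", m, ncol(X))
  v <- apply(X, 2L, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(m)])
  X[, keep, drop = FALSE]
}

## views of any supported dataset object, in training orientation
dataset_views <- function(data) {
  if (inherits(data, "confounded_omics")) {
    list(X1 = data$confounded1, X2 = data$confounded2)
  } else if (inherits(data, "paired_omics")) {
    list(X1 = data$view1, X2 = data$view2)
  } else if (is.list(data) && !is.null(data$X1) && !is.null(data$X2)) {
    list(X1 = as.matrix(data$X1), X2 = as.matrix(data$X2))
  } else {
    stopf("unsupported dataset object of class '%s'", paste(class(data), collapse = "/"))
  }
}

#' Write / read omics matrices and label vectors as delimited text
#'
#' Matrices are stored as TSV with the sample identifier in the first
#' column and feature identifiers in the header; labels and confounders as
#' two-column CSV (`sample_id,value`).
#'
#' @param X Numeric matrix with sample ids as rownames.
#' @param path File path.
#' @return `read_omics_tsv` returns a numeric matrix; `read_labels_csv` a
#'   named vector.
#' @export
write_omics_tsv <- function(X, path) {
  df <- data.frame(sample_id = rownames(X) %||% sprintf("S%04d", seq_len(nrow(X))),
                   X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_omics_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' @rdname write_omics_tsv
#' @param labels Vector with sample ids as names.
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(sample_id = names(labels) %||% sprintf("S%04d", seq_along(labels)),
                   value = unname(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(df$value, df$sample_id)
}
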