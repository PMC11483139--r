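## KMeans with several random initialisations, best inertia kept.
## Caller is responsible for seeding.
seeded_kmeans <- function(X, k, nstart = 10L) {
  if (k > nrow(X)) stopf("k (%d) exceeds number of samples (%d)", k, nrow(X))
  ## Hartigan-Wong emits benign Quick-TRANSfer notes on near-duplicate
  ## rows; fall back to Lloyd on hard failures.
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart,
                                   iter.max = 100L)),
    error = function(e) stats::kmeans(X, centers = k, nstart = nstart,
                                      iter.max = 100L, algorithm = "Lloyd")
  )
  as.integer(km$cluster)
}

#' Co-assignment matrix of one clustering
#'
#' Binary n x n matrix with entry (i, j) equal to 1 iff samples i and j
#' share a cluster label; the diagonal is 1. These matrices are averaged
#' into the consensus matrix.
#'
#' @param labels Cluster label vector.
#' @return n x n binary matrix.
#' @export
coassignment_matrix <- function(labels) {
  if (anyNA(labels)) stopf("labels must be finite")
  outer(labels, labels, "==") * 1
}

#' Build a consensus matrix from sampled embeddings
#'
#' Runs KMeans(k) (with `kmeans_inits` random initialisations, best
#' inertia kept) on each sampled embedding matrix and averages the
#' co-assignment matrices: `A_bar = (1/n_draws) * sum(A_i)`. Entries are
#' co-clustering frequencies in `[0, 1]` and exact multiples of
#' `1/n_draws`; the matrix is symmetric with unit diagonal.
#'
#' @param embeddings List of n x d embedding matrices (e.g. from
#'   [sample_latent()]).
#' @param k Number of clusters.
#' @param kmeans_inits Random initialisations per KMeans run.
#' @param seed Integer seed (one derived seed per draw).
#' @return Object of class `consensus_matrix`: list with `matrix` (n x n),
#'   `n_draws` and `k`.
#' @export
build_consensus <- function(embeddings, k, kmeans_inits = 10L, seed = 1L) {
  if (length(embeddings) < 1L) stopf("need at least one embedding")
  n <- nrow(embeddings[[1]])
  if (k > n) stopf("k (%d) exceeds number of samples (%d)", k, n)
  acc <- matrix(0, n, n)
  for (i in seq_along(embeddings)) {
    lab <- with_seed(derive_seed(seed, i),
                     seeded_kmeans(as.matrix(embeddings[[i]]), k, kmeans_inits))
    acc <- acc + coassignment_matrix(lab)
  }
  structure(list(matrix = acc / length(embeddings),
                 n_draws = length(embeddings), k = as.integer(k)),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("consensus_matrix: %d samples, %d draws, k=%d, dispersion=%.3f\n",
              nrow(x$matrix), x$n_draws, x$k, dispersion(x)))
  invisible(x)
}

#' Spectral clustering of a consensus matrix
#'
#' Normalised spectral clustering (Ng–Jordan–Weiss) using the consensus
#' matrix directly as the affinity: the top-k eigenvectors of
#' `D^{-1/2} A D^{-1/2}` are row-normalised and partitioned by KMeans.
#' If the graph has more than k connected components a warning is
#' emitted; k clusters are still returned (components are merged by
#' their embedding distances).
#'
#' @param cm A [build_consensus()] result, or a bare symmetric affinity
#'   matrix.
#' @param k Number of clusters.
#' @param seed Integer seed for the KMeans step.
#' @param kmeans_inits Random KMeans initialisations.
#' @return Integer cluster labels of length n.
#' @export
spectral_cluster <- function(cm, k, seed = 1L, kmeans_inits = 10L) {
  A <- if (inherits(cm, "consensus_matrix")) cm$matrix else as.matrix(cm)
  n <- nrow(A)
  if (k > n) stopf("k (%d) exceeds number of samples (%d)", k, n)
  if (k == 1L) return(rep(1L, n))
  dg <- rowSums(A)
  dg[dg <= 0] <- 1e-12
  S <- A / sqrt(dg) / rep(sqrt(dg), each = n)
  S <- (S + t(S)) / 2
  ei <- eigen(S, symmetric = TRUE)
  n_comp <- sum(ei$values > 1 - 1e-8)
  if (n_comp > k) {
    warning(sprintf("consensus graph has %d components but k = %d; merging by embedding distance",
                    n_comp, k))
  }
  V <- ei$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(V^2))
  rn[rn == 0] <- 1
  V <- V / rn
  with_seed(seed, seeded_kmeans(V, k, kmeans_inits))
}

#' Consensus clustering of a trained model's latent space
#'
#' End-to-end: encode the full dataset, draw `n_draws` embeddings from the
#' latent posterior, KMeans each, aggregate the co-assignments into a
#' consensus matrix, and partition it by spectral clustering. For the
#' feature-selection variant, pass `keep_dims` (from
#' [filter_latent_features()]): the dropped dimensions are removed from
#' every sampled embedding before KMeans.
#'
#' @param model A trained `xvae`-family model.
#' @param data Dataset object (views must match what the model was
#'   trained on).
#' @param k Number of clusters.
#' @param n_draws Number of sampled embeddings (default 50).
#' @param seed Integer seed for sampling and clustering.
#' @param keep_dims Optional integer vector of latent dimensions to keep.
#' @param kmeans_inits Random KMeans initialisations per draw.
#' @return List with `labels`, the `consensus` matrix object, and the
#'   `posterior` used.
#' @export
consensus_cluster_pipeline <- function(model, data, k, n_draws = 50L,
                                       seed = 1L, keep_dims = NULL,
                                       kmeans_inits = 10L) {
  v <- dataset_views(data)
  post <- encode(model, v$X1, v$X2)
  draws <- sample_latent(post, n_draws = n_draws, seed = derive_seed(seed, 1L))
  if (!is.null(keep_dims)) {
    draws <- lapply(draws, function(Z) Z[, keep_dims, drop = FALSE])
  }
  cm <- build_consensus(draws, k, kmeans_inits = kmeans_inits,
                        seed = derive_seed(seed, 2L))
  labels <- spectral_cluster(cm, k, seed = derive_seed(seed, 3L),
                             kmeans_inits = kmeans_inits)
  list(labels = labels, consensus = cm, posterior = post)
}
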