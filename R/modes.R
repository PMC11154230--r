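#' Longest common subsequence length
#'
#' Length of the longest (not necessarily contiguous) subsequence common to
#' two integer label sequences, by dynamic programming.
#'
#' @param x,y Integer vectors.
#' @return Nonnegative integer.
#' @export
lcs_length <- function(x, y) {
  lcs_length_cpp(as.integer(x), as.integer(y))
}

#' LCS distance between two label sequences
#'
#' `d(x, y) = |x| + |y| - 2 LCS(x, y)`: a metric on label sequences that is
#' sensitive to the order in which labels appear.
#'
#' @inheritParams lcs_length
#' @return Nonnegative number.
#' @export
lcs_distance <- function(x, y) {
  length(x) + length(y) - 2 * lcs_length(x, y)
}

#' Pairwise LCS distance matrix of a fingerprint set
#'
#' @param labels Integer matrix, rows = fingerprints (equal length), or the
#'   list returned by [fingerprint_ensemble()].
#' @return Symmetric N x N numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(labels) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  labels <- as.matrix(labels)
  if (nrow(labels) < 2L) stop("need at least 2 fingerprints")
  storage.mode(labels) <- "integer"
  lcs_distance_matrix_cpp(labels)
}

#' Cluster fingerprints into execution modes
#'
#' Partitions a precomputed LCS distance matrix with one of three
#' techniques: agglomerative hierarchical clustering (average linkage,
#' the default), spectral clustering (normalized-Laplacian embedding of a
#' Gaussian affinity derived from the distances, then k-means), or HDBSCAN
#' (see [hdbscan_distance()]); HDBSCAN chooses its own number of clusters
#' and labels noise points 0.
#'
#' @param dm Symmetric distance matrix.
#' @param method `"agglomerative"`, `"spectral"` or `"hdbscan"`.
#' @param n_clusters Number of clusters (required for agglomerative and
#'   spectral; ignored by hdbscan).
#' @param seed Integer seed controlling the stochastic steps (k-means
#'   initialization); the other methods are deterministic.
#' @param min_cluster_size HDBSCAN minimum cluster size (default 5).
#' @return Integer vector of mode assignments (1..k; 0 = hdbscan noise).
#' @export
cluster_modes <- function(dm, method = c("agglomerative", "spectral",
                                         "hdbscan"),
                          n_clusters = NULL, seed = 1L,
                          min_cluster_size = 5L) {
  method <- match.arg(method)
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n != ncol(dm) || any(abs(dm - t(dm)) > 1e-8) || any(diag(dm) != 0)) {
    stop("dm must be a symmetric distance matrix with zero diagonal")
  }
  if (method %in% c("agglomerative", "spectral")) {
    if (is.null(n_clusters)) stop("n_clusters is required for ", method)
    if (n_clusters > n) stop("n_clusters exceeds the number of fingerprints")
  }
  switch(method,
    agglomerative = {
      hc <- stats::hclust(stats::as.dist(dm), method = "average")
      unname(stats::cutree(hc, k = n_clusters))
    },
    spectral = spectral_cluster(dm, n_clusters, seed),
    hdbscan = hdbscan_distance(dm, min_cluster_size = min_cluster_size))
}

## Ng-Jordan-Weiss spectral clustering on a precomputed distance matrix:
## Gaussian affinity (bandwidth = median positive distance), normalized
## Laplacian embedding, row-normalized leading eigenvectors, k-means.
spectral_cluster <- function(dm, k, seed) {
  n <- nrow(dm)
  if (k == 1L) return(rep(1L, n))
  pos <- dm[upper.tri(dm)]
  sigma <- stats::median(pos[pos > 0])
  if (!length(pos[pos > 0]) || !is.finite(sigma) || sigma == 0) sigma <- 1
  A <- exp(-dm^2 / (2 * sigma^2))
  diag(A) <- 0
  d <- rowSums(A)
  d[d == 0] <- 1e-12
  Dhalf <- 1 / sqrt(d)
  L <- Dhalf * t(Dhalf * A)  # D^{-1/2} A D^{-1/2}, symmetric
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 20L, iter.max = 100L)
  unname(km$cluster)
}

#' Select the number of clusters by mean silhouette
#'
#' Scans `k_range`, clusters the precomputed distance matrix at each `k`
#' and returns the `k` maximizing the mean silhouette width (ties break to
#' the smallest `k`). A degenerate all-zero matrix yields 1 with a warning.
#'
#' @param dm Symmetric distance matrix.
#' @param method Clustering method (passed to [cluster_modes()]; must take
#'   `n_clusters`, i.e. agglomerative or spectral).
#' @param k_range Candidate cluster counts (within `[2, N-1]`).
#' @param seed Seed for stochastic methods.
#' @return The selected number of clusters.
#' @export
select_n_clusters <- function(dm, method = "agglomerative",
                              k_range = 2:8, seed = 1L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (all(dm == 0)) {
    warning("degenerate all-zero distance matrix; returning 1 cluster")
    return(1L)
  }
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("k_range has no valid entries in [2, N-1]")
  sil <- vapply(k_range, function(k) {
    cl <- cluster_modes(dm, method = method, n_clusters = k, seed = seed)
    if (length(unique(cl)) < 2L) return(-Inf)
    mean(cluster::silhouette(cl, dmatrix = dm)[, "sil_width"])
  }, numeric(1))
  as.integer(k_range[which.max(sil)])
}

#' Assemble execution modes from cluster assignments
#'
#' An execution mode is a cluster of fingerprints carrying (i) the summed
#' normalized posterior weight of its member parameter vectors as its
#' probability and (ii) the most frequent subnetwork label among its
#' members' fingerprints as its representative dominant subnetwork.
#'
#' @param assignments Integer vector of cluster ids (0 allowed for hdbscan
#'   noise, reported as its own mode).
#' @param ensemble The [parameter_ensemble()] the fingerprints came from.
#' @param fingerprints Fingerprint label matrix (rows aligned with the
#'   ensemble), or the list from [fingerprint_ensemble()].
#' @return An `execution_modes` object: data frame `summary` (mode_id,
#'   n_members, probability, representative_label) plus `assignments` and
#'   `members`.
#' @export
execution_modes <- function(assignments, ensemble, fingerprints = NULL) {
  if (!is.null(fingerprints) && is.list(fingerprints) &&
      !is.null(fingerprints$labels)) {
    fingerprints <- fingerprints$labels
  }
  n <- length(assignments)
  if (n != length(ensemble)) {
    stop("assignments and ensemble sizes differ")
  }
  ids <- sort(unique(assignments))
  members <- lapply(ids, function(m) which(assignments == m))
  prob <- mode_probabilities(members, ensemble)
  rep_lab <- vapply(members, function(idx) {
    if (is.null(fingerprints)) return(NA_integer_)
    representative_label(fingerprints[idx, , drop = FALSE])
  }, integer(1))
  structure(list(
    summary = data.frame(mode_id = ids,
                         n_members = lengths(members),
                         probability = prob,
                         representative_label = rep_lab),
    assignments = assignments,
    members = stats::setNames(members, ids)),
    class = "execution_modes")
}

#' @export
print.execution_modes <- function(x, ...) {
  cat("execution_modes:", nrow(x$summary), "mode(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Posterior-weighted mode probabilities
#'
#' The probability of a mode is the sum of the normalized posterior weights
#' of its member parameter vectors; over any partition of the ensemble the
#' probabilities sum to 1.
#'
#' @param members List of integer index vectors (one per mode, partitioning
#'   the ensemble).
#' @param ensemble A [parameter_ensemble()].
#' @return Numeric vector of probabilities, one per mode.
#' @export
mode_probabilities <- function(members, ensemble) {
  idx <- sort(as.integer(unlist(members)))
  if (!identical(idx, seq_len(length(ensemble)))) {
    stop("modes must partition the ensemble exactly")
  }
  vapply(members, function(i) sum(ensemble$weights[i]), numeric(1))
}

## Most frequent label in a fingerprint block; ties break to the smaller
## label.
representative_label <- function(label_block) {
  tab <- table(as.integer(label_block))
  labs <- as.integer(names(tab))
  best <- labs[tab == max(tab)]
  min(best)
}

#' Representative dominant subnetwork of a mode
#'
#' The subnetwork label with the highest total occurrence count across the
#' mode's member fingerprints, decoded to its canonical edge list.
#'
#' @param modes An [execution_modes()] object.
#' @param mode_id Which mode.
#' @param fingerprints Fingerprint label matrix or [fingerprint_ensemble()]
#'   result.
#' @param registry The label registry used to build the fingerprints.
#' @return A `dominant_subnetwork`-like list with `label` and `edges`.
#' @export
representative_subnetwork <- function(modes, mode_id, fingerprints,
                                      registry) {
  if (is.list(fingerprints) && !is.null(fingerprints$labels)) {
    fingerprints <- fingerprints$labels
  }
  idx <- modes$members[[as.character(mode_id)]]
  if (is.null(idx) || !length(idx)) stop("empty or unknown mode: ", mode_id)
  lab <- representative_label(fingerprints[idx, , drop = FALSE])
  list(label = lab, edges = registry_edges(registry, lab))
}
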