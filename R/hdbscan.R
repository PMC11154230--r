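#' HDBSCAN clustering on a precomputed distance matrix
#'
#' Hierarchical density-based clustering (Campello-Moulavi-Sander) operating
#' directly on a distance matrix: core distances at `min_cluster_size`
#' neighbors, mutual-reachability transform, single-linkage hierarchy,
#' condensation of the hierarchy at `min_cluster_size`, and excess-of-mass
#' cluster extraction by stability. Points that never join a stable cluster
#' are labeled 0 (noise); callers treating the result as a partition should
#' keep label 0 as its own (noise) mode.
#'
#' Merge heights of zero (exact duplicate fingerprints) are floored at half
#' the smallest positive height so density (1/height) stays finite; a fully
#' degenerate all-zero matrix yields a single cluster.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @param min_cluster_size Minimum number of members of a real cluster
#'   (>= 2; also used as the core-distance neighborhood size).
#' @return Integer assignments: 1..k for clusters, 0 for noise.
#' @export
hdbscan_distance <- function(dm, min_cluster_size = 5L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  mcs <- as.integer(min_cluster_size)
  if (mcs < 2L) stop("min_cluster_size must be >= 2")
  if (n <= mcs) return(rep(1L, n))
  ## core distance: distance to the mcs-th nearest neighbor (self included)
  core <- vapply(seq_len(n), function(i) sort(dm[i, ])[mcs], numeric(1))
  mr <- pmax(dm, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  heights <- hc$height
  pos <- heights[heights > 0]
  if (!length(pos)) return(rep(1L, n))  # all mutual-reachability ties
  hmin <- min(pos) / 2
  lam <- function(h) 1 / max(h, hmin)

  ## members of each dendrogram node (merge rows are height-ordered)
  members <- vector("list", n - 1L)
  node_members <- function(j) if (j < 0) -j else members[[j]]
  for (i in seq_len(n - 1L)) {
    members[[i]] <- c(node_members(hc$merge[i, 1L]),
                      node_members(hc$merge[i, 2L]))
  }
  node_size <- function(j) if (j < 0) 1L else length(members[[j]])

  ## condensed cluster tree built by a top-down walk of the dendrogram
  birth <- numeric(0); stability <- numeric(0)
  children <- list(); points <- list()
  new_cluster <- function(b, pts) {
    birth[[length(birth) + 1L]] <<- b
    stability[[length(stability) + 1L]] <<- 0
    children[[length(children) + 1L]] <<- integer(0)
    points[[length(points) + 1L]] <<- pts
    length(birth)
  }
  root <- new_cluster(0, seq_len(n))
  stack <- list(list(node = n - 1L, cid = root))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top$node; cid <- top$cid
    l <- lam(heights[node])
    ch <- hc$merge[node, ]
    sizes <- c(node_size(ch[1L]), node_size(ch[2L]))
    big <- sizes >= mcs
    if (all(big)) {
      ## true split: current cluster dies here, two children are born
      stability[cid] <- stability[cid] +
        sum(sizes) * (l - lam_birth(birth[cid], l))
      for (b in 1:2) {
        cc <- new_cluster(l, node_members(ch[b]))
        children[[cid]] <- c(children[[cid]], cc)
        stack[[length(stack) + 1L]] <- list(node = ch[b], cid = cc)
      }
    } else if (any(big)) {
      ## runt split: the small side falls out, the cluster continues
      small <- which(!big); keep <- which(big)
      stability[cid] <- stability[cid] +
        sizes[small] * (l - lam_birth(birth[cid], l))
      stack[[length(stack) + 1L]] <- list(node = ch[keep], cid = cid)
    } else {
      ## both sides below min_cluster_size: remaining points fall out
      stability[cid] <- stability[cid] +
        sum(sizes) * (l - lam_birth(birth[cid], l))
    }
  }

  k_all <- length(birth)
  if (k_all == 1L) {
    ## no condensed split anywhere: one diffuse cluster
    return(rep(1L, n))
  }
  ## excess-of-mass: bottom-up stability comparison (children were created
  ## after their parents, so reverse creation order is a valid traversal)
  selected <- rep(FALSE, k_all)
  subtree <- numeric(k_all)
  for (cid in rev(seq_len(k_all))) {
    kids <- children[[cid]]
    if (!length(kids)) {
      selected[cid] <- TRUE
      subtree[cid] <- stability[cid]
    } else if (cid != root &&
               stability[cid] >= sum(subtree[kids])) {
      selected[cid] <- TRUE
      subtree[cid] <- stability[cid]
    } else {
      subtree[cid] <- sum(subtree[kids])
    }
  }
  ## top-down assignment: stop at the shallowest selected cluster
  assign <- rep(0L, n)
  mode_id <- 0L
  walk <- c(root)
  while (length(walk)) {
    cid <- walk[1L]; walk <- walk[-1L]
    if (selected[cid]) {
      mode_id <- mode_id + 1L
      assign[points[[cid]]] <- mode_id
    } else {
      walk <- c(walk, children[[cid]])
    }
  }
  assign
}

## birth lambdas of the root are 0 ("born at infinite distance"); guard so
## stability increments are never negative when a floored height sits above
## the birth level.
lam_birth <- function(b, l) min(b, l)
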