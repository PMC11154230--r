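test_that("LCS length and distance match hand-worked examples", {
  expect_equal(lcs_length(c(1, 2, 3), c(1, 3)), 2L)
  expect_equal(lcs_length(c(1, 2, 3), c(1, 2, 3)), 3L)
  expect_equal(lcs_length(c(1, 1), c(2, 2)), 0L)
  expect_equal(lcs_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(lcs_distance(c(1, 2, 3), c(1, 3)), 1)
  expect_equal(lcs_distance(c(1, 1), c(2, 2)), 4)
})

test_that("LCS length equals exhaustive enumeration for short sequences", {
  set.seed(5)
  for (rep in 1:60) {
    x <- sample(1:4, sample(1:8, 1), replace = TRUE)
    y <- sample(1:4, sample(1:8, 1), replace = TRUE)
    expect_equal(lcs_length(x, y), brute_force_lcs(x, y))
  }
})

test_that("LCS distance satisfies the metric axioms", {
  set.seed(9)
  for (rep in 1:350) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    z <- sample(1:5, 12, replace = TRUE)
    dxy <- lcs_distance(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, lcs_distance(y, x))
    expect_equal(lcs_distance(x, x), 0)
    if (dxy == 0) expect_equal(lcs_length(x, y), length(x))
    expect_lte(dxy, lcs_distance(x, z) + lcs_distance(z, y))
  }
})

test_that("distance matrix is symmetric, zero-diagonal, and N x N", {
  labs <- rbind(c(1, 1, 2), c(1, 2, 2), c(1, 1, 2), c(3, 3, 3))
  dm <- distance_matrix(labs)
  expect_equal(dim(dm), c(4L, 4L))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), rep(0, 4))
  expect_equal(dm[1, 3], 0)           # duplicated fingerprints
  expect_equal(dm[1, 2], 2)           # one substitution = distance 2
  expect_equal(dm[1, 4], 6)           # disjoint alphabets: maximal
  expect_error(distance_matrix(labs[1, , drop = FALSE]), "at least 2")
})

test_that("clustering splits duplicate groups and respects permutations", {
  labs <- rbind(matrix(rep(c(1, 1, 1, 2), 5), 5, 4, byrow = TRUE),
                matrix(rep(c(3, 3, 4, 4), 5), 5, 4, byrow = TRUE))
  dm <- distance_matrix(labs)
  truth <- rep(1:2, each = 5)
  for (m in c("agglomerative", "spectral")) {
    cl <- cluster_modes(dm, method = m, n_clusters = 2, seed = 3)
    expect_equal(length(unique(cl)), 2L)
    expect_true(all(table(cl, truth) %in% c(0L, 5L)))
  }
  # permuting rows/columns permutes assignments identically (up to relabel)
  perm <- c(7, 2, 9, 4, 1, 6, 3, 8, 5, 10)
  cl <- cluster_modes(dm, n_clusters = 2)
  cl_perm <- cluster_modes(dm[perm, perm], n_clusters = 2)
  expect_true(all(table(cl[perm], cl_perm) %in% c(0L, 5L)))
  expect_error(cluster_modes(dm, n_clusters = 99), "exceeds")
  expect_error(cluster_modes(dm, method = "kmedoids"))
})

test_that("hdbscan finds duplicate groups and handles degenerate input", {
  labs <- rbind(matrix(rep(c(1, 1, 1, 2), 6), 6, 4, byrow = TRUE),
                matrix(rep(c(3, 3, 4, 4), 6), 6, 4, byrow = TRUE))
  cl <- hdbscan_distance(distance_matrix(labs), min_cluster_size = 3)
  expect_equal(length(unique(cl[cl != 0])), 2L)
  expect_true(all(table(cl, rep(1:2, each = 6)) %in% c(0L, 6L)))
  # all-identical fingerprints: a single mode, no noise
  same <- matrix(1L, 6, 4)
  expect_equal(hdbscan_distance(distance_matrix(same)), rep(1L, 6))
})

test_that("silhouette selection recovers the planted number of groups", {
  labs <- rbind(matrix(rep(c(1, 1, 1, 1), 5), 5, 4, byrow = TRUE),
                matrix(rep(c(2, 2, 2, 2), 5), 5, 4, byrow = TRUE))
  expect_equal(select_n_clusters(distance_matrix(labs), k_range = 2:5), 2L)
  same <- matrix(1L, 5, 4)
  expect_warning(k <- select_n_clusters(distance_matrix(same)),
                 "degenerate")
  expect_equal(k, 1L)
})

test_that("mode probabilities sum member weights and conserve mass", {
  ens_u <- parameter_ensemble(matrix(1, 4, 2,
                                     dimnames = list(NULL, c("a", "b"))))
  p <- mode_probabilities(list(c(1, 2), 3, 4), ens_u)
  expect_equal(p, c(0.5, 0.25, 0.25))
  ens_w <- parameter_ensemble(matrix(1, 4, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              weights = c(0.4, 0.3, 0.2, 0.1))
  p2 <- mode_probabilities(list(c(1, 2), c(3, 4)), ens_w)
  expect_equal(p2, c(0.7, 0.3))
  expect_equal(sum(p2), 1)
  # invariance to mode relabeling (order of the member list)
  expect_equal(mode_probabilities(list(c(3, 4), c(1, 2)), ens_w),
               rev(p2))
  expect_error(mode_probabilities(list(c(1, 2), 3), ens_w), "partition")
})

test_that("representative subnetwork is the modal label, ties to smaller", {
  reg <- new_registry()
  canonical_label(list(edges = data.frame(from = "A", to = "B",
                                          reaction = "r")), reg)   # label 1
  canonical_label(list(edges = data.frame(from = "B", to = "C",
                                          reaction = "r")), reg)   # label 2
  ens <- parameter_ensemble(matrix(1, 4, 1, dimnames = list(NULL, "k")))
  fps <- rbind(c(1, 1, 1), c(1, 1, 2), c(2, 2, 2), c(2, 2, 1))
  modes <- execution_modes(c(1, 1, 2, 2), ens, fps)
  expect_equal(modes$summary$representative_label, c(1L, 2L))
  rs <- representative_subnetwork(modes, 1, fps, reg)
  expect_equal(rs$label, 1L)
  expect_equal(paste(rs$edges$from, rs$edges$to), "A B")
  # exact tie between labels 1 and 2 resolves to the smaller label
  tie <- rbind(c(1, 1, 2), c(2, 2, 1))
  m2 <- execution_modes(c(1, 1),
                        parameter_ensemble(matrix(1, 2, 1,
                                                  dimnames = list(NULL, "k"))),
                        tie)
  expect_equal(m2$summary$representative_label, 1L)
})
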