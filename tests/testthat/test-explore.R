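test_that("embedding + clustering is deterministic and recovers planted blobs", {
  m <- two_blob_matrix(n_per = 50, seed = 3)
  truth <- attr(m, "truth")
  e1 <- embed_and_cluster(m, n_neighbors = 15, min_pts = 5, seed = 11)
  e2 <- embed_and_cluster(m, n_neighbors = 15, min_pts = 5, seed = 11)
  expect_identical(e1, e2)
  e3 <- embed_and_cluster(m, n_neighbors = 15, min_pts = 5, seed = 12)
  expect_false(isTRUE(all.equal(e1$x, e3$x)))

  expect_equal(length(unique(e1$cluster[e1$cluster > 0])), 2)
  expect_equal(mclust::adjustedRandIndex(e1$cluster, truth), 1)
  expect_equal(e1$coord_sum, e1$x + e1$y)
})

test_that("degenerate clustering parameters give all-noise labels", {
  m <- two_blob_matrix(n_per = 10, seed = 5)
  e <- embed_and_cluster(m, n_neighbors = 5, min_pts = 25, seed = 1)
  expect_true(all(e$cluster == 0))
  expect_error(embed_and_cluster(m, n_neighbors = 30, seed = 1),
               class = "rasnet_data_error")
})

test_that("hdbscan labels: single compact cloud is one cluster, minPts monotone", {
  set.seed(8)
  X <- matrix(rnorm(80), ncol = 2)
  expect_true(all(hdbscan_labels(X, 5) == hdbscan_labels(X, 5)))
  # non-increasing cluster count as minPts grows on fixed coordinates
  set.seed(9)
  Y <- rbind(cbind(rnorm(30, 0, 0.3), rnorm(30, 0, 0.3)),
             cbind(rnorm(30, 4, 0.3), rnorm(30, 4, 0.3)),
             cbind(rnorm(30, 0, 0.3), rnorm(30, 6, 0.3)))
  scan <- scan_min_pts(Y, c(5, 10, 20, 35))
  expect_true(all(diff(scan$n_clusters) <= 0))
  expect_equal(scan$n_clusters[1], 3)  # three planted blobs at moderate minPts
})

test_that("validity indices match brute-force oracles and flag degenerate input", {
  set.seed(14)
  for (rep in 1:6) {
    X <- matrix(rnorm(60), ncol = 2)
    cl <- sample(1:3, 30, replace = TRUE)
    got <- clustering_indices(X, cl)
    ref <- oracle_indices(X, cl)
    expect_equal(got$c_index, ref$c_index, tolerance = 1e-9)
    expect_equal(got$calinski_harabasz, ref$calinski_harabasz, tolerance = 1e-9)
    expect_equal(got$silhouette, ref$silhouette, tolerance = 1e-9)
  }
  und <- clustering_indices(matrix(rnorm(20), ncol = 2), rep(1L, 10))
  expect_false(und$defined)
  expect_true(is.na(und$c_index))
})

test_that("indices are invariant to label permutation and rigid motions", {
  set.seed(15)
  X <- matrix(rnorm(60), ncol = 2)
  cl <- sample(1:3, 30, replace = TRUE)
  base <- clustering_indices(X, cl)
  relab <- c(3L, 1L, 2L)[cl]
  expect_equal(clustering_indices(X, relab), base)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- X %*% R + matrix(c(5, -2), 30, 2, byrow = TRUE)
  rot <- clustering_indices(moved, cl)
  expect_equal(rot$c_index, base$c_index, tolerance = 1e-9)
  expect_equal(rot$calinski_harabasz, base$calinski_harabasz, tolerance = 1e-9)
  expect_equal(rot$silhouette, base$silhouette, tolerance = 1e-9)
})

test_that("C-index hits 0 when within-cluster pairs are the globally closest", {
  # two tight pairs far apart: within distances are the two smallest
  X <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1))
  got <- clustering_indices(X, c(1, 1, 2, 2))
  expect_equal(got$c_index, 0)
  expect_gt(got$silhouette, 0.95)  # compact far-apart clusters
})

test_that("stability iterations are reproducible and track clusters", {
  m <- two_blob_matrix(n_per = 20, n_feat = 10, seed = 6)
  s1 <- stability_iterations(m, n_iter = 5, n_neighbors = 10, min_pts = 5,
                             base_seed = 100, subset_size = 3)
  s2 <- stability_iterations(m, n_iter = 5, n_neighbors = 10, min_pts = 5,
                             base_seed = 100, subset_size = 3)
  expect_identical(s1$iterations, s2$iterations)
  expect_identical(s1$indices, s2$indices)
  expect_length(s1$lineplot_iterations, 3)
  expect_equal(nrow(s1$indices), 5)
  # coordinate sums reconstructible from stored coordinates
  expect_equal(s1$iterations$coord_sum, s1$iterations$x + s1$iterations$y)
  # single iteration works
  s3 <- stability_iterations(m, n_iter = 1, n_neighbors = 10, base_seed = 1)
  expect_equal(nrow(s3$indices), 1)
  expect_s3_class(glance(s1), "tbl_df")
  expect_s3_class(tidy(s1), "tbl_df")
})

test_that("marker detection recovers a planted shifted reaction", {
  set.seed(20)
  n <- 60
  M <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(sprintf("R%02d", 1:40), sprintf("s%02d", 1:n)))
  labels <- rep(c(1L, 2L), each = n / 2)
  M["R05", labels == 1] <- M["R05", labels == 1] + 5
  mk <- marker_reactions(M, labels)
  top1 <- mk[mk$cluster == 1, ][1, ]
  expect_equal(top1$reaction_id, "R05")
  expect_lt(top1$fdr, 0.01)
  expect_gt(top1$lfc, 4)

  # with exactly two clusters both modes coincide
  mk2 <- marker_reactions(M, labels, mode = "pairwise_max")
  expect_equal(mk$pvalue, mk2$pvalue)

  # constant reaction: p = 1 with zero-variance flag
  M["R10", ] <- 3
  mk3 <- marker_reactions(M, labels)
  r10 <- mk3[mk3$reaction_id == "R10" & mk3$cluster == 1, ]
  expect_equal(r10$pvalue, 1)
  expect_true(r10$zero_variance)
})

test_that("pairwise_max requires separation from every cluster", {
  set.seed(21)
  M <- matrix(rnorm(10 * 60), 10, 60,
              dimnames = list(sprintf("R%02d", 1:10), sprintf("s%02d", 1:60)))
  labels <- rep(1:3, each = 20)
  # R01 separates cluster 1 from cluster 2 but not from cluster 3
  M["R01", labels == 2] <- M["R01", labels == 2] + 6
  vs <- marker_reactions(M, labels, mode = "vs_rest")
  pw <- marker_reactions(M, labels, mode = "pairwise_max")
  p_vs <- vs$pvalue[vs$cluster == 1 & vs$reaction_id == "R01"]
  p_pw <- pw$pvalue[pw$cluster == 1 & pw$reaction_id == "R01"]
  expect_gt(p_pw, p_vs)   # the max-p semantics is more conservative
  expect_gt(p_pw, 0.01)   # not a cluster-1 marker under "all" semantics
  # Welch p-values agree with stats::t.test
  pw1 <- row_welch_check <- rasnet:::row_welch(M, which(labels == 1),
                                               which(labels != 1))
  for (i in c(1, 5, 9)) {
    ref <- stats::t.test(M[i, labels == 1], M[i, labels != 1])
    expect_equal(unname(pw1$p[i]), ref$p.value, tolerance = 1e-12)
  }
})

test_that("marker detection validates cluster structure", {
  M <- matrix(rnorm(40), 4, 10)
  expect_error(marker_reactions(M, rep(1L, 10)), class = "rasnet_data_error")
  # one singleton cluster: it is skipped (warning) and, with no valid
  # comparison left, the call errors
  labs <- c(rep(1L, 8), 2L, 0L)
  expect_error(suppressWarnings(marker_reactions(M, labs)),
               class = "rasnet_data_error")
  w <- testthat::capture_warnings(try(marker_reactions(M, labs), silent = TRUE))
  expect_true(any(grepl("fewer than 2", w)))
})
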