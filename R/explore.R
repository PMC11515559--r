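#' Embed samples with UMAP and cluster the embedding
#'
#' Projects the samples of a (scaled, adjusted) reaction x sample matrix
#' into two dimensions with UMAP and finds density clusters of samples on
#' the embedding coordinates with HDBSCAN ([hdbscan_labels()]). UMAP's
#' stochastic layout is made reproducible by seeding the random number
#' generator and running single-threaded, so identical calls with the same
#' seed return identical coordinates and labels.
#'
#' @param M Numeric matrix with samples in columns (e.g. the output of
#'   [scale_reactions()]).
#' @param n_neighbors UMAP neighborhood size; the sample count must exceed
#'   it. Small values (3) emphasize local structure for small cohorts;
#'   12-20 suit cohorts of a hundred samples or more.
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param min_pts HDBSCAN minimum cluster size (default 5).
#' @param seed Integer seed.
#' @return A tibble of class `ras_embedding` with columns `sample`, `x`,
#'   `y`, `coord_sum` (x + y, used by the stability line plots) and
#'   `cluster` (integer, 0 = noise/outlier pseudo-cluster).
#' @export
embed_and_cluster <- function(M, n_neighbors = 15, min_dist = 0.1,
                              min_pts = 5, seed = 42) {
  stopifnot(is.matrix(M))
  n <- ncol(M)
  if (n < n_neighbors + 1) {
    abort(sprintf("Need at least n_neighbors + 1 = %d samples, got %d.",
                  n_neighbors + 1, n), class = "rasnet_data_error")
  }
  X <- t(unclass(M))
  set.seed(seed)
  coords <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  labels <- hdbscan_labels(coords, min_pts = min_pts)
  out <- tibble(
    sample = colnames(M) %||% as.character(seq_len(n)),
    x = coords[, 1], y = coords[, 2],
    coord_sum = coords[, 1] + coords[, 2],
    cluster = as.integer(labels)
  )
  structure(out, class = c("ras_embedding", class(out)),
            seed = seed, n_neighbors = n_neighbors,
            min_dist = min_dist, min_pts = min_pts)
}

#' Internal cluster validity indices on embedding coordinates
#'
#' Computes three internal indices on the Euclidean distances of 2-D
#' embedding coordinates, with noise points (label 0) excluded:
#'
#' * C-index: `(S_w - S_min) / (S_max - S_min)`, where `S_w` is the sum of
#'   within-cluster pairwise distances and `S_min`/`S_max` are the sums of
#'   the equally many smallest/largest pairwise distances overall; 0 means
#'   the within-cluster pairs are exactly the globally closest pairs.
#' * Calinski-Harabasz: ratio of between- to within-cluster dispersion,
#'   `(SSB / (k - 1)) / (SSW / (n - k))`.
#' * Silhouette: mean silhouette width (via [cluster::silhouette()]).
#'
#' @param coords Numeric matrix of coordinates (rows = samples) or a
#'   `ras_embedding`.
#' @param labels Integer cluster labels (0 = noise); taken from the
#'   embedding if `coords` is a `ras_embedding`.
#' @return A one-row tibble with `c_index`, `calinski_harabasz`,
#'   `silhouette`, `n_clusters` and `defined` (FALSE when fewer than two
#'   non-noise clusters exist, in which case the indices are NA).
#' @export
clustering_indices <- function(coords, labels = NULL) {
  if (inherits(coords, "ras_embedding")) {
    labels <- coords$cluster
    coords <- cbind(coords$x, coords$y)
  }
  coords <- as.matrix(coords)
  stopifnot(length(labels) == nrow(coords))
  keep <- labels > 0
  cl <- labels[keep]
  k <- length(unique(cl))
  if (k < 2) {
    return(tibble(c_index = NA_real_, calinski_harabasz = NA_real_,
                  silhouette = NA_real_, n_clusters = k, defined = FALSE))
  }
  X <- coords[keep, , drop = FALSE]
  n <- nrow(X)
  dm <- as.matrix(dist(X))
  pair <- upper.tri(dm)
  dvals <- dm[pair]
  within <- outer(cl, cl, "==")[pair]
  n_w <- sum(within)
  s_w <- sum(dvals[within])
  ds <- sort(dvals)
  s_min <- sum(ds[seq_len(n_w)])
  s_max <- sum(ds[seq.int(length(ds) - n_w + 1L, length(ds))])
  c_index <- if (s_max > s_min) (s_w - s_min) / (s_max - s_min) else NA_real_

  grand <- colMeans(X)
  ssw <- 0
  ssb <- 0
  for (g in unique(cl)) {
    Xi <- X[cl == g, , drop = FALSE]
    ci <- colMeans(Xi)
    ssw <- ssw + sum(sweep(Xi, 2, ci)^2)
    ssb <- ssb + nrow(Xi) * sum((ci - grand)^2)
  }
  ch <- (ssb / (k - 1)) / (ssw / (n - k))

  sil <- mean(cluster::silhouette(cl, dist(X))[, "sil_width"])

  tibble(c_index = c_index, calinski_harabasz = ch, silhouette = sil,
         n_clusters = k, defined = TRUE)
}

#' Repeated embedding for cluster-stability assessment
#'
#' UMAP layouts are heuristic: re-running with a different seed moves the
#' samples even though the local structure is preserved. To judge how
#' stable the clustering is without cherry-picking one layout, the
#' embedding + clustering is repeated `n_iter` times with seeds
#' `base_seed + 1, ..., base_seed + n_iter`, and for each iteration the
#' per-sample coordinate sum (x + y), the cluster labels and the three
#' validity indices are recorded. A random subset of iterations (default
#' 50) is marked for line plotting, where samples that keep their cluster
#' trace parallel lines across iterations.
#'
#' @inheritParams embed_and_cluster
#' @param n_iter Number of iterations (the reference analysis uses 1000).
#' @param base_seed Base seed; iteration i uses `base_seed + i`.
#' @param subset_size Number of iterations marked for the line plot.
#' @return An object of class `ras_stability`: a list with tibbles
#'   `iterations` (iteration, seed, sample, x, y, coord_sum, cluster),
#'   `indices` (per-iteration validity indices) and the integer vector
#'   `lineplot_iterations`.
#' @export
stability_iterations <- function(M, n_iter = 100, n_neighbors = 15,
                                 min_dist = 0.1, min_pts = 5,
                                 base_seed = 42, subset_size = 50) {
  stopifnot(n_iter >= 1)
  iters <- vector("list", n_iter)
  idx <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    emb <- embed_and_cluster(M, n_neighbors = n_neighbors,
                             min_dist = min_dist, min_pts = min_pts,
                             seed = base_seed + i)
    iters[[i]] <- mutate(as_tibble(emb), iteration = i, seed = base_seed + i)
    idx[[i]] <- mutate(clustering_indices(emb), iteration = i)
  }
  set.seed(base_seed)
  subset <- sort(sample(seq_len(n_iter), size = min(subset_size, n_iter)))
  structure(
    list(
      iterations = select(bind_rows(iters), "iteration", "seed", "sample",
                          "x", "y", "coord_sum", "cluster"),
      indices = select(bind_rows(idx), "iteration", "c_index",
                       "calinski_harabasz", "silhouette", "n_clusters",
                       "defined"),
      lineplot_iterations = subset,
      params = list(n_iter = n_iter, n_neighbors = n_neighbors,
                    min_dist = min_dist, min_pts = min_pts,
                    base_seed = base_seed)
    ),
    class = "ras_stability"
  )
}

#' @export
print.ras_stability <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ras_stability> %d iterations, %d samples (n_neighbors=%d, min_pts=%d, base_seed=%d)\n",
    p$n_iter, length(unique(x$iterations$sample)), p$n_neighbors, p$min_pts,
    p$base_seed
  ))
  print(glance(x))
  invisible(x)
}

#' @method tidy ras_stability
#' @export
tidy.ras_stability <- function(x, ...) {
  x$iterations
}

#' @method glance ras_stability
#' @export
glance.ras_stability <- function(x, ...) {
  ok <- x$indices[x$indices$defined, , drop = FALSE]
  tibble(
    n_iter = x$params$n_iter,
    n_defined = nrow(ok),
    median_n_clusters = median(x$indices$n_clusters),
    median_c_index = median(ok$c_index),
    median_calinski_harabasz = median(ok$calinski_harabasz),
    median_silhouette = median(ok$silhouette)
  )
}

#' Stability line plot
#'
#' Per-sample coordinate sums across the plotted subset of iterations,
#' colored by cluster; samples that stay in the same cluster trace
#' parallel bands.
#'
#' @param object A `ras_stability`.
#' @param ... Unused.
#' @method autoplot ras_stability
#' @export
autoplot.ras_stability <- function(object, ...) {
  df <- filter(object$iterations,
               .data$iteration %in% object$lineplot_iterations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$coord_sum,
                                   group = .data$sample,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "iteration", y = "x + y coordinate sum",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Embedding scatter plot
#'
#' @param object A `ras_embedding`.
#' @param colour_by Optional numeric vector (e.g. one reaction's adjusted
#'   activity) named by sample; defaults to the cluster labels.
#' @param ... Unused.
#' @method autoplot ras_embedding
#' @export
autoplot.ras_embedding <- function(object, colour_by = NULL, ...) {
  df <- as_tibble(object)
  if (is.null(colour_by)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          colour = factor(.data$cluster))) +
      ggplot2::labs(colour = "cluster")
  } else {
    df$value <- colour_by[df$sample]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          colour = .data$value)) +
      ggplot2::scale_colour_viridis_c()
  }
  p + ggplot2::geom_point(size = 2) + ggplot2::theme_minimal()
}

#' Write stability tables as TSV
#'
#' @param x A `ras_stability`.
#' @param dir Output directory; writes `stability_iterations.tsv` and
#'   `stability_indices.tsv`.
#' @export
write_stability <- function(x, dir) {
  stopifnot(inherits(x, "ras_stability"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(x$iterations, file.path(dir, "stability_iterations.tsv"))
  readr::write_tsv(x$indices, file.path(dir, "stability_indices.tsv"))
  invisible(dir)
}
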