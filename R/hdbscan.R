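#' HDBSCAN density clustering
#'
#' Hierarchical density-based clustering (HDBSCAN*), used here to find
#' clusters of samples in a 2-D embedding. The algorithm: (1) the core
#' distance of a point is the distance to its `min_pts`-th nearest
#' neighbor (counting the point itself); (2) mutual reachability distance
#' between two points is the maximum of their core distances and their
#' Euclidean distance; (3) single-linkage clustering on mutual
#' reachability distances yields a density hierarchy; (4) the hierarchy is
#' condensed so that only components of at least `min_pts` points count as
#' clusters, points peeling off smaller components fall out of their
#' parent cluster; (5) the flat clustering maximizing total stability
#' (excess of mass) is selected. Points belonging to no selected cluster
#' are noise and receive the pseudo-cluster label 0; real clusters are
#' labelled 1..k.
#'
#' @param X Numeric matrix, observations in rows.
#' @param min_pts Minimum cluster size / density smoothing parameter. If
#'   `min_pts` exceeds the number of observations every point is noise.
#' @return Integer vector of cluster labels (0 = noise).
#' @references Campello, Moulavi & Sander (2013), Density-based clustering
#'   based on hierarchical density estimates.
#' @export
hdbscan_labels <- function(X, min_pts = 5) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  n <- nrow(X)
  if (min_pts < 2) abort("min_pts must be >= 2.", class = "rasnet_data_error")
  if (min_pts > n) return(rep(0L, n))

  d <- as.matrix(dist(X))
  core <- vapply(seq_len(n), function(i) {
    sort(d[i, -i], partial = min_pts - 1)[min_pts - 1]
  }, numeric(1))
  mrd <- pmax(d, outer(core, core, pmax))
  diag(mrd) <- 0
  hc <- stats::hclust(stats::as.dist(mrd), method = "single")

  condensed <- condense_tree(hc, min_pts, n)
  select_eom(condensed, n)
}

# Build the condensed cluster tree from a single-linkage hierarchy.
# Returns per-cluster parent/birth/stability and per-point assignment
# (the cluster each point fell out of, with its lambda).
condense_tree <- function(hc, min_pts, n) {
  merge <- hc$merge
  height <- hc$height
  m <- nrow(merge)

  # leaf count and member list per internal node
  members <- vector("list", m)
  for (k in seq_len(m)) {
    get_members <- function(id) {
      if (id < 0) -id else members[[id]]
    }
    members[[k]] <- c(get_members(merge[k, 1]), get_members(merge[k, 2]))
  }

  lambda_of <- function(h) if (h <= 0) Inf else 1 / h

  parent <- integer()      # parent cluster id (0 for root)
  birth <- numeric()       # lambda at which the cluster appears
  stability <- numeric()
  has_children <- logical()
  point_cluster <- integer(n)   # cluster each point fell out of
  point_lambda <- numeric(n)

  new_cluster <- function(par, lam) {
    parent <<- c(parent, par)
    birth <<- c(birth, lam)
    stability <<- c(stability, 0)
    has_children <<- c(has_children, FALSE)
    length(parent)
  }

  root <- new_cluster(0L, 0)
  # stack entries: (tree node id, cluster the node's points belong to)
  stack <- list(list(node = m, cluster = root))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    cl <- top$cluster
    lam <- lambda_of(height[node])
    ch <- merge[node, ]
    sz <- vapply(ch, function(id) if (id < 0) 1L else length(members[[id]]),
                 integer(1))
    big <- sz >= min_pts

    drop_points <- function(id) {
      pts <- if (id < 0) -id else members[[id]]
      point_cluster[pts] <<- cl
      point_lambda[pts] <<- lam
      stability[cl] <<- stability[cl] + length(pts) * (lam - birth[cl])
    }

    if (all(big)) {
      # true split: current cluster dies, two children are born
      stability[cl] <- stability[cl] + sum(sz) * (lam - birth[cl])
      has_children[cl] <- TRUE
      for (id in ch) {
        child <- new_cluster(cl, lam)
        stack[[length(stack) + 1L]] <- list(node = id, cluster = child)
      }
    } else if (any(big)) {
      drop_points(ch[!big])
      stack[[length(stack) + 1L]] <- list(node = ch[big], cluster = cl)
    } else {
      drop_points(ch[1])
      drop_points(ch[2])
    }
  }

  list(parent = parent, birth = birth, stability = stability,
       has_children = has_children,
       point_cluster = point_cluster, point_lambda = point_lambda)
}

# Excess-of-mass cluster selection; root excluded. Returns labels 1..k
# (0 = noise). If no split ever happened the data form one cluster.
select_eom <- function(ct, n) {
  k <- length(ct$parent)
  if (k == 1L) return(rep(1L, n))  # condensed tree is only the root

  children <- split(seq_len(k)[-1], ct$parent[-1])
  selected <- logical(k)
  subtree_score <- numeric(k)

  # process in reverse creation order: children always have larger ids
  for (cl in rev(seq_len(k))) {
    ch <- children[[as.character(cl)]]
    if (is.null(ch)) {
      subtree_score[cl] <- ct$stability[cl]
      selected[cl] <- TRUE
    } else {
      child_sum <- sum(subtree_score[ch])
      if (cl == 1L || ct$stability[cl] < child_sum) {
        subtree_score[cl] <- child_sum
        selected[cl] <- FALSE
      } else {
        subtree_score[cl] <- ct$stability[cl]
        selected[cl] <- TRUE
        # deselect the whole subtree
        desc <- ch
        while (length(desc) > 0) {
          selected[desc] <- FALSE
          desc <- unlist(children[as.character(desc)])
        }
      }
    }
  }
  selected[1L] <- FALSE  # root never selected

  # map every point to the nearest selected ancestor of its record cluster
  labels <- integer(n)
  sel_ids <- which(selected)
  relabel <- stats::setNames(seq_along(sel_ids), sel_ids)
  for (p in seq_len(n)) {
    cl <- ct$point_cluster[p]
    while (cl != 0L && !selected[cl]) cl <- ct$parent[cl]
    labels[p] <- if (cl == 0L) 0L else relabel[[as.character(cl)]]
  }
  labels
}

#' Scan HDBSCAN minimum cluster sizes
#'
#' Tabulates the clustering at a range of `min_pts` values on fixed
#' coordinates -- the practical way to choose `min_pts`: prefer a value
#' where the number of outliers is small and cluster sizes are moderate.
#' The number of clusters is non-increasing in `min_pts`.
#'
#' @param X Numeric coordinate matrix (observations in rows).
#' @param min_pts_values Integer vector of candidate values.
#' @return A tibble with columns `min_pts`, `n_clusters`, `n_noise`.
#' @export
scan_min_pts <- function(X, min_pts_values = c(3, 5, 10, 15, 20)) {
  rows <- lapply(min_pts_values, function(mp) {
    labels <- hdbscan_labels(as.matrix(X), min_pts = mp)
    tibble(min_pts = mp,
           n_clusters = length(unique(labels[labels > 0])),
           n_noise = sum(labels == 0))
  })
  bind_rows(rows)
}
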