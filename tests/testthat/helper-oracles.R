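# Independent reference implementations used to validate package results.
# These deliberately share no code with the package internals.

# median-of-ratios size factors, straight from the definition
oracle_size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  apply(counts, 2, function(col) {
    exp(median(log(col[use]) - log_gm[use]))
  })
}

# edge-traversal probabilities from x by exhaustive DFS over simple paths
oracle_path_tp <- function(edges, tp_lookup, x, combine = "sum") {
  # edges: data.frame(source, target); tp_lookup: function(i, j) -> plain TP
  out <- new.env(parent = emptyenv())
  adj <- split(edges$target, edges$source)
  walk <- function(node, visited, prob) {
    for (nxt in adj[[node]]) {
      if (nxt %in% visited) next
      p <- prob * tp_lookup(node, nxt)
      key <- paste(node, nxt)
      prev <- if (is.null(out[[key]])) 0 else out[[key]]
      out[[key]] <- if (combine == "sum") prev + p else max(prev, p)
      walk(nxt, c(visited, nxt), p)
    }
  }
  walk(x, x, 1)
  as.list(out)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# exact two-sample KS p-value by enumerating all group assignments
oracle_ks_D <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  Fa <- vapply(pool, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pool, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

oracle_ks_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  d_obs <- oracle_ks_D(a, b)
  picks <- utils::combn(length(pool), n)
  hits <- 0L
  for (j in seq_len(ncol(picks))) {
    aa <- pool[picks[, j]]
    bb <- pool[-picks[, j]]
    if (oracle_ks_D(aa, bb) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(picks)
}

# clustering validity indices with naive double loops
oracle_indices <- function(X, cl) {
  n <- nrow(X)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) dmat[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  dv <- c()
  within <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      dv <- c(dv, dmat[i, j])
      within <- c(within, cl[i] == cl[j])
    }
  }
  nw <- sum(within)
  sw <- sum(dv[within])
  srt <- sort(dv)
  cidx <- (sw - sum(srt[1:nw])) /
    (sum(rev(srt)[1:nw]) - sum(srt[1:nw]))

  k <- length(unique(cl))
  grand <- colMeans(X)
  ssb <- 0
  ssw <- 0
  for (g in unique(cl)) {
    Xi <- X[cl == g, , drop = FALSE]
    ci <- colMeans(Xi)
    for (r in seq_len(nrow(Xi))) ssw <- ssw + sum((Xi[r, ] - ci)^2)
    ssb <- ssb + nrow(Xi) * sum((ci - grand)^2)
  }
  ch <- (ssb / (k - 1)) / (ssw / (n - k))

  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { sil[i] <- 0; next }
    a_i <- mean(dmat[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(dmat[i, cl == g])
    }, numeric(1)))
    sil[i] <- (b_i - a_i) / max(a_i, b_i)
  }

  list(c_index = cidx, calinski_harabasz = ch, silhouette = mean(sil))
}
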