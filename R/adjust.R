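#' Adjust a RAS matrix with a transition-probability scheme
#'
#' Combines the per-sample weighted adjacency W with one of the three
#' transition-probability matrices, element-wise, and re-serializes the
#' edge weights into the reaction x sample layout:
#'
#' * `"W1"`: W * T, the plain row-normalized TP ([transition_matrix()]);
#' * `"W2"`: W * T^a, the recursive adjustment ([recursive_tp()]);
#' * `"W3"`: W * T^b, the path-product adjustment from source node `x`
#'   ([path_tp()]).
#'
#' `"W"` returns the unadjusted matrix (useful when iterating over scheme
#' lists). Since every TP of schemes W1 and W2 lies in \[0, 1\], those
#' adjustments never increase an activity, and on a branchless chain all
#' three schemes are the identity.
#'
#' @param ras A `ras_matrix` from [compute_ras()].
#' @param graph The [metabolic_graph] the RAS was computed on.
#' @param scheme One of `"W"`, `"W1"`, `"W2"`, `"W3"`.
#' @param x Source metabolite for scheme `"W3"` (default `"C01290"`,
#'   lactosylceramide).
#' @param combine,max_paths Passed to [path_tp()] for scheme `"W3"`.
#' @return A `ras_matrix` with attribute `scheme` set accordingly.
#' @export
adjust_ras <- function(ras, graph, scheme = c("W1", "W2", "W3", "W"),
                       x = "C01290", combine = c("sum", "max"),
                       max_paths = 1e5) {
  scheme <- match.arg(scheme)
  combine <- match.arg(combine)
  stopifnot(inherits(graph, "metabolic_graph"), is.matrix(ras))
  if (!setequal(rownames(ras), graph$edges$edge_id) ||
      nrow(ras) != nrow(graph$edges)) {
    abort("RAS matrix rows do not match the graph's reaction set.",
          class = "rasnet_data_error")
  }
  ras <- ras[graph$edges$edge_id, , drop = FALSE]
  if (scheme == "W") {
    return(new_ras_matrix(unclass(ras), scheme = "W"))
  }
  ids <- graph$nodes$id
  eidx <- cbind(match(graph$edges$source, ids),
                match(graph$edges$target, ids))
  path_steps <- NULL
  if (scheme == "W3") {
    if (!x %in% ids) {
      abort(sprintf("Source node '%s' is not in the graph.", x),
            class = "rasnet_data_error")
    }
    # enumeration depends only on structure; reuse across samples
    paths <- enumerate_simple_paths(graph, x, max_paths)
    path_steps <- lapply(paths, function(p) {
      cbind(match(p[-length(p)], ids), match(p[-1], ids))
    })
  }

  out <- matrix(0, nrow(ras), ncol(ras), dimnames = dimnames(ras))
  overflow <- FALSE
  for (s in seq_len(ncol(ras))) {
    W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    W[eidx] <- as.numeric(ras[, s])
    Tp <- transition_matrix(W)
    Tm <- switch(scheme,
      W1 = Tp,
      W2 = recursive_tp(Tp, graph),
      W3 = {
        Tb <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
        Tpm <- unclass(Tp)
        for (st in path_steps) {
          pr <- prod(Tpm[st])
          last <- st[nrow(st), , drop = FALSE]
          if (combine == "sum") Tb[last] <- Tb[last] + pr
          else Tb[last] <- max(Tb[last], pr)
        }
        if (any(Tb > 1 + 1e-9)) overflow <- TRUE
        Tb
      }
    )
    out[, s] <- unclass(Tm)[eidx] * as.numeric(ras[, s])
  }
  if (overflow) {
    warn("Some path-summed transition probabilities exceed 1 (cyclic graph?).",
         class = "rasnet_tp_overflow")
  }
  new_ras_matrix(out, scheme = scheme)
}

#' Scale an adjusted RAS matrix for embedding
#'
#' Path-adjusted activities shrink with path length, so their variances
#' differ by orders of magnitude across reactions; standardizing each
#' reaction row to mean 0 and unit variance makes the scores homoscedastic
#' before a UMAP embedding. Reactions outside any possible path (all-zero
#' rows) are removed first, and rows that are constant across samples are
#' dropped with a warning since they carry no information.
#'
#' @param adj A `ras_matrix` (typically scheme `"W3"`).
#' @return A reaction x sample matrix with row means 0 and row standard
#'   deviations 1.
#' @export
scale_reactions <- function(adj) {
  stopifnot(is.matrix(adj))
  if (ncol(adj) < 2) {
    abort("Scaling needs at least 2 samples.", class = "rasnet_data_error")
  }
  m <- unclass(adj)[rowSums(abs(adj)) > 0, , drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d constant reaction row(s) before scaling.",
                 sum(sds == 0)), class = "rasnet_constant_rows")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (m - rowMeans(m)) / sds
}
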