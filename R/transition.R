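#' Plain transition-probability matrix of a weighted graph
#'
#' Row-normalizes a non-negative weighted adjacency matrix W: the
#' transition probability `t[i, j] = w[i, j] / sum_k w[i, k]` is the
#' probability that a one-step random walker in node i moves to node j,
#' where edge weights are the per-sample reaction activities. Rows whose
#' outgoing activities are all zero are set to zero rather than uniform:
#' zero expression means zero activity, so no flow is invented.
#'
#' @param W Square, non-negative numeric matrix (see
#'   [sample_adjacency()]).
#' @return A `tp_matrix` with attribute `variant = "plain"`.
#' @export
transition_matrix <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) {
    abort("Adjacency weights must be non-negative.", class = "rasnet_data_error")
  }
  rs <- rowSums(W)
  T_ <- W / ifelse(rs > 0, rs, 1)
  T_[rs == 0, ] <- 0
  new_tp_matrix(T_, variant = "plain")
}

new_tp_matrix <- function(values, variant, source_node = NULL) {
  structure(values, variant = variant, source_node = source_node,
            class = c("tp_matrix", class(matrix())))
}

#' @export
print.tp_matrix <- function(x, ...) {
  cat(sprintf("<tp_matrix variant=%s%s> %d x %d\n",
              attr(x, "variant"),
              if (!is.null(attr(x, "source_node")))
                paste0(" from ", attr(x, "source_node")) else "",
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Recursive transition-probability adjustment
#'
#' Reactions that are a node's only outgoing edge carry a plain transition
#' probability of 1, so parallel pathway series built from chains of such
#' edges stay indistinguishable. This adjustment replaces every entry
#' equal to 1 by the largest plain TP among the incoming edges of its
#' source node; if that incoming TP is itself 1 the search recurses
#' upstream until a value different from 1 is found. A node with no
#' incoming edges keeps TP 1, and a cycle consisting solely of TP-1 edges
#' also resolves to 1. All lookups use the original plain matrix, making
#' the result independent of edge processing order, and entries below 1
#' are never touched.
#'
#' @param T_plain A plain `tp_matrix` (from [transition_matrix()]).
#' @param graph The [metabolic_graph] the matrix was built from (provides
#'   the edge structure).
#' @return A `tp_matrix` with attribute `variant = "recursive"`.
#' @export
recursive_tp <- function(T_plain, graph) {
  check_tp_variant(T_plain, "plain")
  stopifnot(inherits(graph, "metabolic_graph"))
  ids <- rownames(T_plain)
  stopifnot(!is.null(ids), identical(ids, colnames(T_plain)))
  incoming <- split(graph$edges$source, graph$edges$target)

  resolve <- function(node, visited) {
    ins <- incoming[[node]]
    if (is.null(ins) || length(ins) == 0) return(1)
    tps <- T_plain[cbind(ins, node)]
    best <- max(tps)
    src <- sort(ins[tps == best])[1]  # ties: lexicographically smallest source
    if (abs(best - 1) > tp_one_tol) return(best)
    if (src %in% visited) return(1)   # all-1 cycle stays 1
    resolve(src, c(visited, node))
  }

  out <- unclass(T_plain)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$source[k]
    j <- graph$edges$target[k]
    if (abs(T_plain[i, j] - 1) <= tp_one_tol) {
      out[i, j] <- resolve(i, character())
    }
  }
  new_tp_matrix(out, variant = "recursive")
}

tp_one_tol <- 1e-12

#' Path-product transition-probability adjustment
#'
#' Propagates transition probabilities from a chosen source metabolite
#' along all simple paths, like the product rule along branches of a tree
#' diagram: each simple path from `x` carries the product of the plain TPs
#' of its edges, and the new value of an edge is the combination (sum by
#' default) of the products of all simple paths that end with that edge.
#' On a DAG the summed value is exactly the probability that a random walk
#' started in `x` traverses the edge. Edges lying on no simple path from
#' `x` -- unreachable parts of a graph that is not strongly connected --
#' get probability 0. For the glycosphingolipid graph the natural source
#' is lactosylceramide (`C01290`), where the pathway splits into the
#' lacto-/neolacto-, globo- and ganglio-series.
#'
#' @param T_plain A plain `tp_matrix`.
#' @param graph The corresponding [metabolic_graph].
#' @param x Source metabolite (node id).
#' @param combine How to combine the products of several simple paths
#'   ending on the same edge: `"sum"` (default; edge-traversal probability
#'   on DAGs) or `"max"`.
#' @param max_paths Hard cap on the number of enumerated simple paths;
#'   exceeding it is an error (path counts can explode on dense graphs).
#' @return A `tp_matrix` with attributes `variant = "path"` and
#'   `source_node = x`. On cyclic graphs summed values can exceed 1; they
#'   are reported as-is with a warning.
#' @export
path_tp <- function(T_plain, graph, x = "C01290", combine = c("sum", "max"),
                    max_paths = 1e5) {
  combine <- match.arg(combine)
  check_tp_variant(T_plain, "plain")
  stopifnot(inherits(graph, "metabolic_graph"))
  if (!x %in% graph$nodes$id) {
    abort(sprintf("Source node '%s' is not in the graph.", x),
          class = "rasnet_data_error")
  }
  paths <- enumerate_simple_paths(graph, x, max_paths)
  out <- matrix(0, nrow(T_plain), ncol(T_plain),
                dimnames = dimnames(T_plain))
  Tm <- unclass(T_plain)
  for (p in paths) {
    # p is a vector of node ids x, v1, ..., vk
    steps <- cbind(p[-length(p)], p[-1])
    prod_tp <- prod(Tm[steps])
    last <- steps[nrow(steps), , drop = FALSE]
    if (combine == "sum") {
      out[last] <- out[last] + prod_tp
    } else {
      out[last] <- max(out[last], prod_tp)
    }
  }
  if (any(out > 1 + 1e-9)) {
    warn("Some path-summed transition probabilities exceed 1 (cyclic graph?).",
         class = "rasnet_tp_overflow")
  }
  new_tp_matrix(out, variant = "path", source_node = x)
}

# All simple paths from x, as a list of node-id vectors (length >= 2).
# Structure-only, so the enumeration can be reused across samples.
enumerate_simple_paths <- function(graph, x, max_paths = 1e5) {
  g <- as_igraph(graph)
  paths <- igraph::all_simple_paths(g, from = x, mode = "out", cutoff = -1)
  if (length(paths) > max_paths) {
    abort(sprintf(
      "Simple-path enumeration from '%s' exceeded max_paths = %g.",
      x, max_paths
    ), class = "rasnet_path_explosion")
  }
  lapply(paths, function(p) igraph::as_ids(p))
}

check_tp_variant <- function(T_, variant) {
  if (!inherits(T_, "tp_matrix") || !identical(attr(T_, "variant"), variant)) {
    abort(sprintf("Expected a '%s' tp_matrix.", variant),
          class = "rasnet_variant_error")
  }
  invisible(TRUE)
}
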