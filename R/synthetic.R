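#' Toy branch-and-chains graph with shared step enzymes
#'
#' A fixed nine-node graph reproducing the topological situation that
#' motivates the transition-probability adjustments: a branch node `s`
#' feeds two parallel chains (`s -> a -> c -> e -> g` and
#' `s -> b -> d -> f -> h`), the two branch reactions carry distinct
#' genes, and each downstream step of the two chains is catalyzed by one
#' and the same gene (`g_step1` on both a->c and b->d, and so on) -- the
#' promiscuous-enzyme pattern of parallel ganglioside series. The
#' unadjusted activities of corresponding chain steps are therefore
#' identical for any expression, while the recursive and path adjustments
#' separate them whenever the two branch activities differ.
#'
#' @return A [metabolic_graph] with 9 nodes and 8 reactions.
#' @export
toy_graph_fig3 <- function() {
  edges <- tibble(
    reaction_id = c("R_sa", "R_sb", "R_ac", "R_bd", "R_ce", "R_df",
                    "R_eg", "R_fh"),
    source = c("s", "s", "a", "b", "c", "d", "e", "f"),
    target = c("a", "b", "c", "d", "e", "f", "g", "h"),
    gpr = c("g_branch_a", "g_branch_b", "g_step1", "g_step1",
            "g_step2", "g_step2", "g_step3", "g_step3"),
    pathways = "toy"
  )
  nodes <- tibble(
    id = c("s", "a", "c", "e", "g", "b", "d", "f", "h"),
    label = c("branch", rep("chain A", 4), rep("chain B", 4)),
    series_tag = c("other", rep("a-series", 4), rep("b-series", 4))
  )
  metabolic_graph(edges, nodes = nodes)
}

#' Random directed acyclic graph with single-gene reactions
#'
#' Generates a topologically ordered DAG: nodes `n01 < n02 < ...` and an
#' edge for each ordered pair with probability `edge_prob`. Every edge
#' carries its own single-gene GPR, so activities can be assigned freely.
#' Used as the substrate for brute-force validation of the path-product
#' adjustment.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param edge_prob Edge probability in \[0, 1\].
#' @param seed Integer seed; output is fully reproducible.
#' @return A [metabolic_graph]. With `edge_prob = 0` the graph has no
#'   edges (and is returned with an empty edge set).
#' @export
random_dag <- function(n_nodes, edge_prob, seed = 1) {
  stopifnot(n_nodes >= 2, edge_prob >= 0, edge_prob <= 1)
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  take <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[take, , drop = FALSE]
  if (nrow(pairs) == 0) {
    g <- metabolic_graph(
      tibble(reaction_id = "Rtmp", source = ids[1], target = ids[2],
             gpr = "gtmp", pathways = "sim"))
    g$edges <- g$edges[0, ]
    g$nodes <- tibble(id = ids, label = ids, series_tag = NA_character_)
    g$gene_universe <- character()
    return(g)
  }
  edges <- tibble(
    reaction_id = sprintf("R%03d", seq_len(nrow(pairs))),
    source = ids[pairs[, 1]],
    target = ids[pairs[, 2]],
    gpr = sprintf("gene%03d", seq_len(nrow(pairs))),
    pathways = "sim"
  )
  metabolic_graph(edges,
                  nodes = tibble(id = ids, label = ids,
                                 series_tag = NA_character_))
}

#' Specification for grouped negative-binomial count simulation
#'
#' Bundles the parameters of [simulate_counts()]: samples per group,
#' negative-binomial mean and dispersion, group effects on named genes,
#' optional unaffected background genes, and the seed. Bulk RNA-seq
#' counts are over-dispersed relative to Poisson; the negative binomial
#' with a gene-level dispersion (default 0.1, a typical bulk value) is
#' the standard model.
#'
#' @param n_per_group Samples in each of groups A and B (length 1 or 2).
#' @param base_mean Mean raw count per gene (recycled over genes).
#' @param dispersion Negative-binomial dispersion; variance is
#'   `mu + dispersion * mu^2`. Must be positive.
#' @param effects Data frame with columns `gene`, `log2_effect`, `group`:
#'   the gene's mean is multiplied by `2^log2_effect` in that group.
#' @param n_background Extra genes outside the graph, unaffected by
#'   effects.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_group = 30, base_mean = 100, dispersion = 0.1,
                         effects = NULL, n_background = 0, seed = 1) {
  if (any(dispersion <= 0) || any(base_mean <= 0)) {
    abort("base_mean and dispersion must be positive.",
          class = "rasnet_data_error")
  }
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    stopifnot(all(c("gene", "log2_effect", "group") %in% names(effects)))
  }
  structure(
    list(n_per_group = rep(n_per_group, length.out = 2),
         base_mean = base_mean, dispersion = dispersion,
         effects = effects, n_background = n_background, seed = seed),
    class = "fixture_spec"
  )
}

#' Simulate grouped negative-binomial counts for a graph
#'
#' Draws raw counts for every gene of the graph (plus optional background
#' genes) in two sample groups A and B. Group effects from the spec
#' multiply the affected gene's mean by `2^log2_effect` in the named
#' group; all other genes are exchangeable between groups, which makes
#' the no-effect configuration a null-calibration input.
#'
#' @param graph A [metabolic_graph]; its `gene_universe` defines the
#'   simulated graph genes.
#' @param spec A [fixture_spec()].
#' @return A list with `counts` (integer gene x sample matrix) and
#'   `annotations` (tibble with columns `sample`, `group`).
#' @export
simulate_counts <- function(graph, spec = fixture_spec()) {
  stopifnot(inherits(graph, "metabolic_graph"), inherits(spec, "fixture_spec"))
  genes <- graph$gene_universe
  if (spec$n_background > 0) {
    genes <- c(genes, sprintf("bg%04d", seq_len(spec$n_background)))
  }
  if (!is.null(spec$effects)) {
    bad <- setdiff(spec$effects$gene, genes)
    if (length(bad) > 0) {
      abort(sprintf("Effect gene(s) not among simulated genes: %s",
                    paste(bad, collapse = ", ")), class = "rasnet_data_error")
    }
  }
  nA <- spec$n_per_group[1]
  nB <- spec$n_per_group[2]
  samples <- c(sprintf("A%03d", seq_len(nA)), sprintf("B%03d", seq_len(nB)))
  group <- rep(c("A", "B"), c(nA, nB))
  mu <- matrix(rep(spec$base_mean, length.out = length(genes)),
               nrow = length(genes), ncol = nA + nB,
               dimnames = list(genes, samples))
  if (!is.null(spec$effects)) {
    for (i in seq_len(nrow(spec$effects))) {
      g <- spec$effects$gene[i]
      grp <- spec$effects$group[i]
      mu[g, group == grp] <- mu[g, group == grp] * 2^spec$effects$log2_effect[i]
    }
  }
  set.seed(spec$seed)
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / spec$dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  list(counts = counts,
       annotations = tibble(sample = samples, group = group))
}

#' Write fixture data in the package's ingestion dialects
#'
#' Writes the graph edge table, counts TSV and annotation TSV of a
#' simulated fixture into a directory, in exactly the formats
#' [read_graph_table()] and [read_counts()] read back.
#'
#' @param graph A [metabolic_graph].
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(graph, sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_graph_table(graph, file.path(dir, "graph.tsv"))
  counts <- as.data.frame(sim$counts)
  counts <- cbind(gene = rownames(sim$counts), counts)
  readr::write_tsv(counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
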