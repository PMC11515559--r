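#' Construct a metabolite-centric metabolic graph
#'
#' The central container of the package is a directed, metabolite-centric
#' graph: nodes are metabolites (e.g. KEGG compounds) and each edge is a
#' metabolic reaction converting the source metabolite into the target,
#' annotated with the [GPR rule][parse_gpr] of the catalyzing enzyme(s) and
#' the pathway(s) the reaction belongs to. At most one edge exists per
#' ordered node pair, so per-sample reaction activities define a single
#' weighted adjacency matrix; when several reactions share a (source,
#' target) pair their GPRs are merged with OR semantics and all reaction
#' ids are retained (`merge_duplicates = TRUE`), or an error is raised
#' (`merge_duplicates = FALSE`, the edge-table ingestion default).
#'
#' @param edges A data frame with columns `reaction_id`, `source`, `target`,
#'   `gpr` (boolean GPR strings, or a list of `gpr_rule` objects) and
#'   `pathways` (semicolon-separated strings, or a list of character
#'   vectors).
#' @param nodes Optional data frame with columns `id` and optionally
#'   `label` and `series_tag`; defaults to the nodes implied by the edges.
#' @param merge_duplicates Merge edges sharing (source, target) with OR
#'   semantics instead of erroring.
#' @return A `metabolic_graph` object with components `nodes` (tibble),
#'   `edges` (tibble, one row per directed edge, keyed by `edge_id`) and
#'   `gene_universe` (character vector of all genes in any GPR).
#' @examples
#' g <- metabolic_graph(data.frame(
#'   reaction_id = c("R1", "R2"),
#'   source = c("C1", "C2"), target = c("C2", "C3"),
#'   gpr = c("GENE1", "GENE2 OR GENE3"),
#'   pathways = "hsa00600"
#' ))
#' g
#' @export
metabolic_graph <- function(edges, nodes = NULL, merge_duplicates = FALSE) {
  edges <- as_tibble(edges)
  req <- c("reaction_id", "source", "target", "gpr", "pathways")
  miss <- setdiff(req, names(edges))
  if (length(miss) > 0) {
    abort(sprintf("Edge table lacks column(s): %s", paste(miss, collapse = ", ")),
          class = "rasnet_graph_error")
  }
  if (nrow(edges) > 0 && any(edges$source == edges$target)) {
    abort("Self-loop edges (source == target) are not allowed.",
          class = "rasnet_graph_error")
  }

  # normalize gpr column to a list of parsed rules
  if (!is.list(edges$gpr)) {
    rules <- vector("list", nrow(edges))
    for (i in seq_len(nrow(edges))) {
      rules[[i]] <- tryCatch(
        parse_gpr(edges$gpr[[i]]),
        error = function(e) abort(
          sprintf("Row %d: cannot parse GPR '%s': %s", i,
                  edges$gpr[[i]], conditionMessage(e)),
          class = "rasnet_gpr_error"
        )
      )
    }
    edges$gpr <- rules
  }
  # normalize pathways to a list of character vectors
  if (!is.list(edges$pathways)) {
    edges$pathways <- strsplit(as.character(edges$pathways), ";", fixed = TRUE)
    edges$pathways <- lapply(edges$pathways, trimws)
  }
  if (nrow(edges) > 0 &&
      any(vapply(edges$pathways, function(p) length(p) == 0 || !any(nzchar(p)),
                 logical(1)))) {
    abort("Every edge needs at least one pathway annotation.",
          class = "rasnet_graph_error")
  }
  edges$reaction_ids <- lapply(edges$reaction_id, identity)

  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    if (!merge_duplicates) {
      dup <- which(duplicated(key))[1]
      abort(sprintf(
        "Duplicate edge for node pair (%s, %s) at row %d.",
        edges$source[dup], edges$target[dup], dup
      ), class = "rasnet_graph_error")
    }
    edges <- merge_parallel_edges(edges, key)
  }

  node_ids <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- tibble(id = node_ids, label = node_ids,
                    series_tag = NA_character_)
  } else {
    nodes <- as_tibble(nodes)
    if (!"id" %in% names(nodes)) {
      abort("Node table needs an 'id' column.", class = "rasnet_graph_error")
    }
    if (anyDuplicated(nodes$id)) {
      abort("Node ids must be unique.", class = "rasnet_graph_error")
    }
    if (!"label" %in% names(nodes)) nodes$label <- nodes$id
    if (!"series_tag" %in% names(nodes)) nodes$series_tag <- NA_character_
    unknown <- setdiff(node_ids, nodes$id)
    if (length(unknown) > 0) {
      abort(sprintf("Edge endpoint(s) missing from node table: %s",
                    paste(unknown, collapse = ", ")),
            class = "rasnet_graph_error")
    }
    nodes <- nodes[, c("id", "label", "series_tag")]
  }

  edges$edge_id <- make_edge_ids(edges)
  edges <- edges[, c("edge_id", "reaction_id", "reaction_ids", "source",
                     "target", "gpr", "pathways")]
  structure(
    list(
      nodes = nodes,
      edges = edges,
      gene_universe = sort(unique(unlist(lapply(edges$gpr, gpr_genes))))
    ),
    class = "metabolic_graph"
  )
}

merge_parallel_edges <- function(edges, key) {
  keep <- !duplicated(key)
  out <- edges[keep, ]
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    i <- which(key[keep] == k)
    rules <- edges$gpr[rows]
    # drop rule duplicates (same deparse) before merging with OR
    sig <- vapply(rules, format, character(1))
    rules <- rules[!duplicated(sig)]
    out$gpr[[i]] <- if (length(rules) == 1L) rules[[1]] else gpr_node("ANY", rules)
    out$reaction_ids[[i]] <- unique(unlist(edges$reaction_ids[rows]))
    out$reaction_id[i] <- out$reaction_ids[[i]][1]
    out$pathways[[i]] <- unique(unlist(edges$pathways[rows]))
  }
  out
}

make_edge_ids <- function(edges) {
  ids <- edges$reaction_id
  dup <- ids %in% ids[duplicated(ids)]
  ids[dup] <- paste(ids[dup], edges$source[dup], edges$target[dup], sep = "_")
  stopifnot(!anyDuplicated(ids))
  ids
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat(sprintf(
    "<metabolic_graph> %d metabolites, %d reactions, %d genes\n",
    nrow(x$nodes), nrow(x$edges), length(x$gene_universe)
  ))
  pw <- sort(unique(unlist(x$edges$pathways)))
  if (length(pw) > 0) {
    cat("pathways:", paste(head(pw, 8), collapse = ", "),
        if (length(pw) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
format.metabolic_graph <- function(x, ...) {
  sprintf("<metabolic_graph: %d nodes, %d edges>", nrow(x$nodes), nrow(x$edges))
}

#' Convert a metabolic graph to an igraph object
#'
#' Edge attributes carry `edge_id`, `reaction_id`, the deparsed GPR string
#' and the semicolon-collapsed pathway set.
#'
#' @param graph A [metabolic_graph].
#' @return An [igraph::igraph] directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "metabolic_graph"))
  el <- data.frame(
    from = graph$edges$source,
    to = graph$edges$target,
    edge_id = graph$edges$edge_id,
    reaction_id = graph$edges$reaction_id,
    gpr = vapply(graph$edges$gpr, format, character(1)),
    pathways = vapply(graph$edges$pathways, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = graph$nodes$id, label = graph$nodes$label,
                          stringsAsFactors = FALSE)
  )
}

#' Parse KGML pathway files into a metabolic graph
#'
#' Reads one or more KGML (KEGG Markup Language) documents and builds the
#' union metabolite-centric graph: compound entries become nodes and every
#' (substrate, product) pair of a reaction becomes one directed edge (a
#' reaction with several substrates or products therefore yields several
#' edges). Reversible reactions emit both directions. Gene entries linked
#' to a reaction become an OR rule over their genes unless `gpr_table`
#' supplies an explicit rule for that reaction id, which takes precedence
#' (GPRs from a curated genome-scale model are more reliable than raw KGML
#' gene lists).
#'
#' @param files Character vector of KGML file paths.
#' @param gpr_table Optional data frame with columns `reaction_id` and
#'   `gpr` overriding KGML-derived gene associations.
#' @param strip_prefix Drop the `"cpd:"`/`"rn:"`/organism (`"hsa:"`)
#'   prefixes from KEGG identifiers (default TRUE).
#' @return A [metabolic_graph].
#' @export
parse_kgml <- function(files, gpr_table = NULL, strip_prefix = TRUE) {
  stopifnot(length(files) >= 1)
  rows <- list()
  for (f in files) {
    doc <- tryCatch(
      xml2::read_xml(f),
      error = function(e) abort(
        sprintf("Malformed KGML file '%s': %s", f, conditionMessage(e)),
        class = "rasnet_parse_error"
      )
    )
    rows[[length(rows) + 1L]] <- kgml_edge_rows(doc, f, strip_prefix)
  }
  edges <- bind_rows(rows)
  if (nrow(edges) == 0) {
    abort("No reactions found in the supplied KGML files.",
          class = "rasnet_parse_error")
  }
  if (!is.null(gpr_table)) {
    gpr_table <- as_tibble(gpr_table)
    stopifnot(all(c("reaction_id", "gpr") %in% names(gpr_table)))
    idx <- match(edges$reaction_id, gpr_table$reaction_id)
    hit <- !is.na(idx)
    edges$gpr[hit] <- gpr_table$gpr[idx[hit]]
  }
  metabolic_graph(edges, merge_duplicates = TRUE)
}

kgml_edge_rows <- function(doc, file, strip_prefix) {
  strip <- function(x) if (strip_prefix) sub("^[a-z]+:", "", x) else x
  pathway_name <- strip(xml2::xml_attr(doc, "name") %||% "unknown")

  entries <- xml2::xml_find_all(doc, ".//entry")
  compounds <- character()
  for (e in entries) {
    if (identical(xml2::xml_attr(e, "type"), "compound")) {
      # an entry may alias several compounds (space-separated)
      ids <- strip(strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]])
      compounds <- c(compounds, ids)
    }
  }
  compounds <- unique(compounds)

  # reaction -> genes, via gene entries carrying a reaction attribute
  rxn_genes <- list()
  for (e in entries) {
    if (identical(xml2::xml_attr(e, "type"), "gene")) {
      rxns <- xml2::xml_attr(e, "reaction")
      if (is.na(rxns)) next
      genes <- strip(strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]])
      for (r in strip(strsplit(rxns, "\\s+")[[1]])) {
        rxn_genes[[r]] <- unique(c(rxn_genes[[r]], genes))
      }
    }
  }

  out <- list()
  for (rx in xml2::xml_find_all(doc, ".//reaction")) {
    rid <- strip(xml2::xml_attr(rx, "name"))
    rid <- strsplit(rid, "\\s+")[[1]][1]
    type <- xml2::xml_attr(rx, "type")
    subs <- strip(xml2::xml_attr(xml2::xml_find_all(rx, ".//substrate"), "name"))
    prods <- strip(xml2::xml_attr(xml2::xml_find_all(rx, ".//product"), "name"))
    bad <- setdiff(c(subs, prods), compounds)
    if (length(bad) > 0) {
      abort(sprintf(
        "Reaction %s in '%s' references unknown compound(s): %s",
        rid, file, paste(bad, collapse = ", ")
      ), class = "rasnet_structure_error")
    }
    genes <- rxn_genes[[rid]]
    gpr <- if (is.null(genes)) rid else paste(genes, collapse = " OR ")
    for (s in subs) {
      for (p in prods) {
        if (s == p) next
        out[[length(out) + 1L]] <- tibble(
          reaction_id = rid, source = s, target = p,
          gpr = gpr, pathways = pathway_name
        )
        if (identical(type, "reversible")) {
          out[[length(out) + 1L]] <- tibble(
            reaction_id = rid, source = p, target = s,
            gpr = gpr, pathways = pathway_name
          )
        }
      }
    }
  }
  bind_rows(out)
}

#' Read and write the tabular graph dialect
#'
#' `read_graph_table()` ingests a TSV edge table with header
#' `reaction_id, source, target, gpr, pathways` (pathways
#' semicolon-separated) -- the same dialect written by
#' `write_graph_table()`, so the two round-trip. Duplicate
#' (source, target) rows are rejected.
#'
#' @param file Path to a TSV file (or, for `read_graph_table()`, a data
#'   frame already in the dialect).
#' @return A [metabolic_graph]; the writer returns `file` invisibly.
#' @export
read_graph_table <- function(file) {
  tab <- if (is.data.frame(file)) {
    as_tibble(file)
  } else {
    readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()))
  }
  metabolic_graph(tab, merge_duplicates = FALSE)
}

#' @rdname read_graph_table
#' @param graph A [metabolic_graph].
#' @export
write_graph_table <- function(graph, file) {
  stopifnot(inherits(graph, "metabolic_graph"))
  tab <- tibble(
    reaction_id = graph$edges$reaction_id,
    source = graph$edges$source,
    target = graph$edges$target,
    gpr = vapply(graph$edges$gpr, format, character(1)),
    pathways = vapply(graph$edges$pathways, paste, character(1), collapse = ";")
  )
  readr::write_tsv(tab, file)
  invisible(file)
}

#' @rdname read_graph_table
#' @export
write_graphml <- function(graph, file) {
  igraph::write_graph(as_igraph(graph), file, format = "graphml")
  invisible(file)
}

#' Remove reactions from a metabolic graph
#'
#' Drops the edges whose reaction ids (or edge ids) are listed; nodes are
#' retained even if they become isolated. Typical use is pruning
#' degradation reactions that are not competing biosynthetic steps, e.g.
#' the GM1-to-GM2 and GM2-to-GM3 degradations (`R06010`, `R06004`) before
#' analyzing ganglioside biosynthesis.
#'
#' @param graph A [metabolic_graph].
#' @param ids Character vector of reaction ids; absent ids produce a
#'   warning, not an error.
#' @return The pruned [metabolic_graph].
#' @export
remove_reactions <- function(graph, ids = c("R06010", "R06004")) {
  stopifnot(inherits(graph, "metabolic_graph"))
  known <- unique(c(graph$edges$edge_id, unlist(graph$edges$reaction_ids)))
  absent <- setdiff(ids, known)
  if (length(absent) > 0) {
    warn(sprintf("Reaction id(s) not in graph: %s",
                 paste(absent, collapse = ", ")),
         class = "rasnet_absent_reaction")
  }
  hit <- graph$edges$edge_id %in% ids |
    vapply(graph$edges$reaction_ids, function(r) any(r %in% ids), logical(1))
  edges <- graph$edges[!hit, ]
  out <- graph
  out$edges <- edges
  out$gene_universe <- sort(unique(unlist(lapply(edges$gpr, gpr_genes))))
  out
}

#' Summarize a metabolic graph
#'
#' Counts reactions by GPR class (AND complexes, OR isoform sets, single
#' genes, nested rules), the number of distinct enzymes (genes) in the
#' graph, and -- when a gene-to-pathway annotation table is supplied -- the
#' number of enzymes also annotated to at least one pathway outside the
#' focal pathway set.
#'
#' @param graph A [metabolic_graph].
#' @param gsl_pathways Character vector of focal pathway ids (used with
#'   `gene_pathways` to count enzymes with outside annotations).
#' @param gene_pathways Optional data frame with columns `gene` and
#'   `pathway` (one row per annotation).
#' @return A one-row tibble with columns `n_reactions`, `n_and`, `n_or`,
#'   `n_single`, `n_nested`, `n_enzymes`, `n_enzymes_outside`.
#' @export
graph_summary <- function(graph, gsl_pathways = NULL, gene_pathways = NULL) {
  stopifnot(inherits(graph, "metabolic_graph"))
  cls <- vapply(graph$edges$gpr, gpr_class, character(1))
  n_outside <- NA_integer_
  if (!is.null(gene_pathways)) {
    gene_pathways <- as_tibble(gene_pathways)
    stopifnot(all(c("gene", "pathway") %in% names(gene_pathways)))
    ann <- gene_pathways[gene_pathways$gene %in% graph$gene_universe, ]
    outside <- ann$gene[!ann$pathway %in% (gsl_pathways %||% character())]
    n_outside <- length(unique(outside))
  }
  tibble(
    n_reactions = nrow(graph$edges),
    n_and = sum(cls == "AND"),
    n_or = sum(cls == "OR"),
    n_single = sum(cls == "single"),
    n_nested = sum(cls == "nested"),
    n_enzymes = length(graph$gene_universe),
    n_enzymes_outside = n_outside
  )
}
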