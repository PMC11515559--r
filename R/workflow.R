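#' Run the end-to-end workflow
#'
#' Orchestrates graph construction, normalization, RAS computation, the
#' requested transition-probability adjustments, and the downstream
#' differential and/or unsupervised analyses, writing all result tables
#' plus a machine-readable run manifest to the output directory. Stages:
#'
#' 1. build graph (edge table or KGML files, optional reaction removal);
#' 2. read counts and annotations, median-of-ratios normalize (optional);
#' 3. compute the RAS matrix;
#' 4. per requested scheme: adjust and write the matrix;
#' 5. differential reaction analysis per scheme (when two groups are
#'    configured) and/or repeated-embedding exploration with markers.
#'
#' Any stage error aborts with the stage name and cause.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized fields (defaults in parentheses): `graph_table` or
#'   `kgml_files`, `counts`, `annotations`, `out_dir`, `schemes`
#'   (`c("W","W1","W2","W3")`), `remove_reactions` (none), `x_node`
#'   (`"C01290"`), `normalize` (TRUE), `alpha` (0.05), `epsilon` (1e-9),
#'   `differential` (TRUE when annotations carry two groups), `explore`
#'   (FALSE), `n_neighbors` (15), `min_dist` (0.1), `min_pts` (5),
#'   `n_iter` (100), `base_seed` (42), `marker_mode` (`"vs_rest"`),
#'   `marker_scheme` (last scheme).
#' @return Invisibly, a named list of written file paths.
#' @export
run_workflow <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Workflow stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "rasnet_workflow_error")
    })
  }

  graph <- stage("build-graph", {
    g <- if (!is.null(cfg$graph_table)) {
      read_graph_table(cfg$graph_table)
    } else if (!is.null(cfg$kgml_files)) {
      parse_kgml(cfg$kgml_files)
    } else {
      abort("Config needs 'graph_table' or 'kgml_files'.")
    }
    if (length(cfg$remove_reactions) > 0) {
      g <- remove_reactions(g, cfg$remove_reactions)
    }
    g
  })
  written$graph <- write_graph_table(graph, file.path(out, "graph.tsv"))

  expr <- stage("normalize", {
    counts <- if (is.character(cfg$counts)) read_counts(cfg$counts) else
      as_count_matrix(cfg$counts)
    if (isTRUE(cfg$normalize)) normalize_counts(counts) else counts
  })
  ann <- stage("annotations", {
    if (is.null(cfg$annotations)) NULL
    else if (is.character(cfg$annotations)) {
      readr::read_tsv(cfg$annotations, show_col_types = FALSE)
    } else as_tibble(cfg$annotations)
  })

  ras <- stage("ras", compute_ras(graph, expr))
  written$ras <- write_ras(ras, file.path(out, "ras_W.tsv"))

  adjusted <- list(W = ras)
  for (sc in setdiff(cfg$schemes, "W")) {
    adjusted[[sc]] <- stage(paste0("adjust-", sc),
                            adjust_ras(ras, graph, scheme = sc, x = cfg$x_node))
    written[[paste0("ras_", sc)]] <-
      write_ras(adjusted[[sc]], file.path(out, sprintf("ras_%s.tsv", sc)))
  }

  do_diff <- cfg$differential %||%
    (!is.null(ann) && length(unique(ann$group)) == 2)
  if (isTRUE(do_diff)) {
    stage("differential", {
      for (sc in cfg$schemes) {
        d <- differential_reactions(adjusted[[sc]], ann,
                                    alpha = cfg$alpha, epsilon = cfg$epsilon)
        written[[paste0("differential_", sc)]] <-
          write_differential(d, file.path(out, sprintf("differential_%s.tsv", sc)))
      }
      pa <- pathway_activity(adjusted[[cfg$schemes[length(cfg$schemes)]]], graph)
      tab <- cbind(pathway = rownames(pa), as.data.frame(pa))
      written$pathway_activity <-
        file.path(out, "pathway_activity.tsv")
      readr::write_tsv(tab, written$pathway_activity)
    })
  }

  if (isTRUE(cfg$explore)) {
    stage("explore", {
      sc <- cfg$marker_scheme %||% cfg$schemes[length(cfg$schemes)]
      scaled <- suppressWarnings(scale_reactions(adjusted[[sc]]))
      stab <- stability_iterations(
        scaled, n_iter = cfg$n_iter, n_neighbors = cfg$n_neighbors,
        min_dist = cfg$min_dist, min_pts = cfg$min_pts,
        base_seed = cfg$base_seed
      )
      write_stability(stab, out)
      written$stability_iterations <- file.path(out, "stability_iterations.tsv")
      written$stability_indices <- file.path(out, "stability_indices.tsv")
      emb <- embed_and_cluster(scaled, n_neighbors = cfg$n_neighbors,
                               min_dist = cfg$min_dist, min_pts = cfg$min_pts,
                               seed = cfg$base_seed)
      readr::write_tsv(as_tibble(emb), file.path(out, "embedding.tsv"))
      written$embedding <- file.path(out, "embedding.tsv")
      if (length(unique(emb$cluster[emb$cluster > 0])) >= 2) {
        mk <- marker_reactions(scaled, emb, mode = cfg$marker_mode)
        readr::write_tsv(as_tibble(mk), file.path(out, "markers.tsv"))
        written$markers <- file.path(out, "markers.tsv")
      }
    })
  }

  manifest <- list(
    package = "rasnet",
    version = as.character(utils::packageVersion("rasnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    outputs = lapply(written, as.character)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  written$manifest <- file.path(out, "manifest.json")
  invisible(written)
}

#' @rdname run_workflow
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file '%s' does not exist.", config),
            class = "rasnet_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("Config must be a named list or a YAML file path.",
          class = "rasnet_config_error")
  }
  defaults <- list(
    schemes = c("W", "W1", "W2", "W3"), remove_reactions = character(),
    x_node = "C01290", normalize = TRUE, alpha = 0.05, epsilon = 1e-9,
    differential = NULL, explore = FALSE, n_neighbors = 15, min_dist = 0.1,
    min_pts = 5, n_iter = 100, base_seed = 42, marker_mode = "vs_rest",
    marker_scheme = NULL, out_dir = "rasnet_run"
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (length(cfg$schemes) == 0) {
    abort("Config field 'schemes' must be non-empty.",
          class = "rasnet_config_error")
  }
  bad <- setdiff(cfg$schemes, c("W", "W1", "W2", "W3"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown scheme(s): %s", paste(bad, collapse = ", ")),
          class = "rasnet_config_error")
  }
  for (f in c("graph_table", "counts", "annotations", "kgml_files")) {
    if (is.character(cfg[[f]])) {
      missing <- cfg[[f]][!file.exists(cfg[[f]])]
      if (length(missing) > 0) {
        abort(sprintf("Config path(s) for '%s' do not exist: %s",
                      f, paste(missing, collapse = ", ")),
              class = "rasnet_config_error")
      }
    }
  }
  cfg
}

#' Export one sample's weighted graph as GraphML
#'
#' Writes the graph with per-edge attributes `ras` (the sample's activity),
#' `tp` (plain transition probability) and `adjusted` (activity times TP
#' under the chosen scheme), for inspection in external graph viewers.
#'
#' @param graph A [metabolic_graph].
#' @param ras A `ras_matrix`.
#' @param sample Sample id.
#' @param file Output path.
#' @param scheme Adjustment scheme for the `adjusted` attribute.
#' @param x Source node for scheme `"W3"`.
#' @export
write_sample_graphml <- function(graph, ras, sample, file,
                                 scheme = "W1", x = "C01290") {
  W <- sample_adjacency(graph, ras, sample)
  Tp <- transition_matrix(W)
  adj <- adjust_ras(ras[, sample, drop = FALSE], graph, scheme = scheme, x = x)
  g <- as_igraph(graph)
  idx <- cbind(graph$edges$source, graph$edges$target)
  igraph::E(g)$ras <- as.numeric(ras[graph$edges$edge_id, sample])
  igraph::E(g)$tp <- unclass(Tp)[idx]
  igraph::E(g)$adjusted <- as.numeric(adj[graph$edges$edge_id, 1])
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
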