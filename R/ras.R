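#' Median-of-ratios normalization with log10 transform
#'
#' Normalizes a raw gene x sample count matrix with the median-of-ratios
#' method: each sample's size factor is the median, over genes with a
#' strictly positive geometric mean across samples, of the ratio between
#' the count and the per-gene geometric mean (the DESeq2 estimator). The
#' normalized counts are then shifted by one pseudocount and log10
#' transformed, so a zero count maps to 0.
#'
#' @param raw Non-negative integer matrix (genes x samples) with rownames
#'   and colnames, or a data frame whose first column holds gene ids.
#' @param log Apply the `log10(x + 1)` transform (default TRUE). Supplying
#'   `log = FALSE` returns size-factor-scaled counts for inspection.
#' @return A numeric gene x sample matrix with attribute `size_factors`.
#' @examples
#' counts <- matrix(rpois(40, 50), 10,
#'                  dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' expr <- normalize_counts(counts)
#' attr(expr, "size_factors")
#' @export
normalize_counts <- function(raw, log = TRUE) {
  raw <- as_count_matrix(raw)
  if (any(raw < 0)) {
    abort("Counts must be non-negative.", class = "rasnet_data_error")
  }
  log_geo <- rowMeans(log(raw))
  if (all(!is.finite(log_geo))) {
    abort(paste0(
      "Every gene has a zero count in some sample, so no reference genes ",
      "exist for the median-of-ratios estimator. Consider a pseudo-reference ",
      "(e.g. add a pseudocount before normalization) or filter samples."
    ), class = "rasnet_data_error")
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(raw)
  out <- sweep(raw, 2, sf, "/")
  if (log) out <- log10(out + 1)
  attr(out, "size_factors") <- sf
  out
}

as_count_matrix <- function(raw) {
  if (is.data.frame(raw)) {
    ids <- raw[[1]]
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- ids
    raw <- m
  }
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (is.null(rownames(raw))) {
    abort("Count matrix needs gene rownames.", class = "rasnet_data_error")
  }
  if (anyDuplicated(rownames(raw))) {
    abort("Gene ids must be unique.", class = "rasnet_data_error")
  }
  raw
}

#' Read a count matrix from TSV/CSV or MatrixMarket files
#'
#' @param file Path to a TSV/CSV file (first column gene ids, remaining
#'   columns samples) or to a MatrixMarket `.mtx` file.
#' @param genes,samples For MTX input: paths to plain-text files holding
#'   the row (gene) and column (sample) names, one per line.
#' @return An integer gene x sample matrix.
#' @export
read_counts <- function(file, genes = NULL, samples = NULL) {
  if (grepl("\\.mtx$", file, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(file))
    if (is.null(genes) || is.null(samples)) {
      abort("MTX input needs 'genes' and 'samples' name files.",
            class = "rasnet_data_error")
    }
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(samples)
    return(m)
  }
  delim <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(file, delim = delim, show_col_types = FALSE)
  as_count_matrix(as.data.frame(tab))
}

#' Compute the Reaction Activity Score matrix
#'
#' For every reaction edge of the graph and every sample, evaluates the
#' edge's GPR rule over the sample's expression column (minimum across AND
#' subunits, sum across OR isoforms; see [evaluate_gpr()]). Reactions that
#' share an identical GPR necessarily receive identical activity rows --
#' the ambiguity the transition-probability adjustments in [adjust_ras()]
#' are designed to break.
#'
#' @param graph A [metabolic_graph].
#' @param expr Normalized gene x sample expression matrix (see
#'   [normalize_counts()]); all values must be non-negative.
#' @param missing_genes Policy for GPR genes absent from `expr`
#'   (see [evaluate_gpr()]).
#' @return A reaction x sample matrix of class `ras_matrix` (rows keyed by
#'   `edge_id`, attribute `scheme = "W"`).
#' @export
compute_ras <- function(graph, expr, missing_genes = c("zero", "error")) {
  missing_genes <- match.arg(missing_genes)
  stopifnot(inherits(graph, "metabolic_graph"), is.matrix(expr))
  if (ncol(expr) == 0 || nrow(expr) == 0) {
    abort("Expression matrix is empty.", class = "rasnet_data_error")
  }
  if (any(expr < 0)) {
    abort("Expression values must be non-negative (normalized, log scale).",
          class = "rasnet_data_error")
  }
  miss <- setdiff(graph$gene_universe, rownames(expr))
  if (length(miss) > 0) {
    msg <- sprintf("%d graph gene(s) absent from expression: %s",
                   length(miss), paste(head(miss, 10), collapse = ", "))
    if (missing_genes == "error") abort(msg, class = "rasnet_missing_gene")
    warn(paste0(msg, "; treated as 0."), class = "rasnet_missing_gene")
  }
  vals <- matrix(0, nrow(graph$edges), ncol(expr),
                 dimnames = list(graph$edges$edge_id, colnames(expr)))
  for (i in seq_len(nrow(graph$edges))) {
    vals[i, ] <- suppressWarnings(
      evaluate_gpr(graph$edges$gpr[[i]], expr, missing_genes = "zero")
    )
  }
  new_ras_matrix(vals, scheme = "W")
}

new_ras_matrix <- function(values, scheme) {
  structure(values, scheme = scheme,
            class = c("ras_matrix", class(matrix())))
}

#' @export
print.ras_matrix <- function(x, ...) {
  cat(sprintf("<ras_matrix scheme=%s> %d reactions x %d samples\n",
              attr(x, "scheme"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Tidy a RAS matrix into long form
#'
#' @param x A `ras_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `reaction_id`, `sample`, `activity`,
#'   `scheme`.
#' @method tidy ras_matrix
#' @export
tidy.ras_matrix <- function(x, ...) {
  tibble(
    reaction_id = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    activity = as.vector(unclass(x)),
    scheme = attr(x, "scheme") %||% "W"
  )
}

#' Per-sample weighted adjacency matrix
#'
#' Serializes one sample's RAS values into the node x node weighted
#' adjacency matrix W of the graph: `W[i, j]` is the activity of the
#' reaction i -> j, and 0 where no edge exists.
#'
#' @param graph A [metabolic_graph].
#' @param ras A `ras_matrix` from [compute_ras()].
#' @param sample Sample id (column of `ras`).
#' @return An n x n numeric matrix with node ids as dimnames.
#' @export
sample_adjacency <- function(graph, ras, sample) {
  stopifnot(inherits(graph, "metabolic_graph"))
  if (!sample %in% colnames(ras)) {
    abort(sprintf("Unknown sample '%s'.", sample), class = "rasnet_data_error")
  }
  ids <- graph$nodes$id
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  idx <- cbind(match(graph$edges$source, ids), match(graph$edges$target, ids))
  W[idx] <- as.numeric(ras[graph$edges$edge_id, sample])
  W
}

#' Write a RAS (or adjusted RAS) matrix as TSV
#'
#' @param ras A `ras_matrix`.
#' @param file Output path; the scheme is recorded in a `# scheme:` header
#'   comment line.
#' @export
write_ras <- function(ras, file) {
  writeLines(sprintf("# scheme: %s", attr(ras, "scheme") %||% "W"), file)
  tab <- as.data.frame(unclass(ras))
  tab <- cbind(reaction_id = rownames(ras), tab)
  readr::write_tsv(tab, file, append = TRUE, col_names = TRUE)
  invisible(file)
}
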