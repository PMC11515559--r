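#' Differential reaction activity between two groups
#'
#' For every reaction, compares the (adjusted) activity distributions of
#' two sample groups: the log2 fold-change of the group means (with a
#' small pseudocount guarding zero means), a two-sided two-sample
#' Kolmogorov-Smirnov test, and Benjamini-Hochberg adjustment across all
#' reactions in the matrix. The KS null distribution is computed exactly
#' when both groups have at most 100 samples and the data are tie-free,
#' and asymptotically otherwise (ties degrade to the asymptotic
#' approximation with a warning).
#'
#' @param M A `ras_matrix` (reaction x sample), adjusted or not.
#' @param groups A factor or character vector named by sample, or a data
#'   frame with columns `sample` and `group`, assigning each sample to one
#'   of exactly two groups. The first factor level plays the role of group
#'   A: positive log2 fold-changes mean higher activity in A.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05, applied to BH-adjusted p-values).
#' @param epsilon Pseudocount in the fold-change,
#'   `log2((mean_A + epsilon) / (mean_B + epsilon))`; default `1e-9`.
#' @return A tibble of class `ras_differential` with columns
#'   `reaction_id`, `mean_A`, `mean_B`, `log2fc`, `ks_D`, `pvalue`,
#'   `padj`, `significant`, ordered as the input rows. Attributes record
#'   the group levels, `alpha`, `epsilon` and the scheme of `M`.
#' @examples
#' M <- matrix(stats::rnorm(40, 5), 4,
#'             dimnames = list(paste0("R", 1:4), paste0("s", 1:10)))
#' grp <- stats::setNames(rep(c("A", "B"), each = 5), colnames(M))
#' differential_reactions(M, grp)
#' @export
differential_reactions <- function(M, groups, alpha = 0.05, epsilon = 1e-9) {
  stopifnot(is.matrix(M))
  groups <- normalize_groups(groups, colnames(M))
  lv <- levels(groups)
  ia <- which(groups == lv[1])
  ib <- which(groups == lv[2])
  if (length(ia) < 2 || length(ib) < 2) {
    abort("Each group needs at least 2 samples.", class = "rasnet_data_error")
  }
  n_tied <- 0L
  res <- lapply(seq_len(nrow(M)), function(i) {
    a <- as.numeric(M[i, ia])
    b <- as.numeric(M[i, ib])
    ties <- anyDuplicated(c(a, b)) > 0
    if (ties) n_tied <<- n_tied + 1L
    exact <- !ties && length(a) <= 100 && length(b) <= 100
    kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
    c(mean_A = mean(a), mean_B = mean(b),
      ks_D = unname(kt$statistic), pvalue = unname(kt$p.value))
  })
  res <- do.call(rbind, res)
  if (n_tied > 0) {
    warn(sprintf(
      "%d reaction(s) had tied values; their KS p-values use the asymptotic approximation.",
      n_tied
    ), class = "rasnet_ks_ties")
  }
  out <- tibble(
    reaction_id = rownames(M) %||% as.character(seq_len(nrow(M))),
    mean_A = unname(res[, "mean_A"]),
    mean_B = unname(res[, "mean_B"]),
    log2fc = unname(log2((res[, "mean_A"] + epsilon) /
                           (res[, "mean_B"] + epsilon))),
    ks_D = unname(res[, "ks_D"]),
    pvalue = unname(res[, "pvalue"])
  )
  out$padj <- bh_adjust(out$pvalue)
  out$significant <- out$padj <= alpha
  structure(
    out,
    class = c("ras_differential", class(out)),
    group_A = lv[1], group_B = lv[2],
    alpha = alpha, epsilon = epsilon,
    scheme = attr(M, "scheme") %||% "W"
  )
}

normalize_groups <- function(groups, samples) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  }
  if (!is.null(samples)) {
    if (is.null(names(groups))) {
      if (length(groups) != length(samples)) {
        abort("Group vector length does not match sample count.",
              class = "rasnet_data_error")
      }
      names(groups) <- samples
    }
    miss <- setdiff(samples, names(groups))
    if (length(miss) > 0) {
      abort(sprintf("No group label for sample(s): %s",
                    paste(head(miss, 5), collapse = ", ")),
            class = "rasnet_data_error")
    }
    groups <- groups[samples]
  }
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2) {
    abort("Exactly two groups are required.", class = "rasnet_data_error")
  }
  groups
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`; input
#' order is preserved and monotonicity is enforced by the step-up
#' construction.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "rasnet_data_error")
  }
  p.adjust(p, method = "BH")
}

#' Pathway-level activity aggregation
#'
#' Sums the (adjusted) activities of all reactions annotated to each
#' pathway, per sample; a reaction annotated to several pathways
#' contributes its value to each of them.
#'
#' @param M A `ras_matrix` whose rows match the graph's reactions.
#' @param graph The [metabolic_graph] carrying pathway annotations.
#' @return A pathway x sample numeric matrix.
#' @export
pathway_activity <- function(M, graph) {
  stopifnot(inherits(graph, "metabolic_graph"), is.matrix(M))
  M <- M[graph$edges$edge_id, , drop = FALSE]
  pws <- sort(unique(unlist(graph$edges$pathways)))
  out <- matrix(0, length(pws), ncol(M), dimnames = list(pws, colnames(M)))
  for (i in seq_len(nrow(graph$edges))) {
    for (p in graph$edges$pathways[[i]]) {
      out[p, ] <- out[p, ] + as.numeric(M[i, ])
    }
  }
  out
}

#' @method glance ras_differential
#' @export
glance.ras_differential <- function(x, ...) {
  tibble(
    n_reactions = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    epsilon = attr(x, "epsilon"),
    group_A = attr(x, "group_A"),
    group_B = attr(x, "group_B"),
    scheme = attr(x, "scheme")
  )
}

#' Write a differential-reaction table as TSV
#'
#' One file per scheme is the intended usage; the scheme is recorded in a
#' header comment.
#'
#' @param x A `ras_differential` table.
#' @param file Output path.
#' @export
write_differential <- function(x, file) {
  writeLines(sprintf("# scheme: %s; A: %s; B: %s; alpha: %g; epsilon: %g",
                     attr(x, "scheme"), attr(x, "group_A"), attr(x, "group_B"),
                     attr(x, "alpha"), attr(x, "epsilon")), file)
  readr::write_tsv(as_tibble(x), file, append = TRUE, col_names = TRUE)
  invisible(file)
}

#' Volcano-style plot of a differential-reaction table
#'
#' @param object A `ras_differential`.
#' @param ... Unused.
#' @return A ggplot object: log2 fold-change vs -log10 adjusted p-value,
#'   significant reactions highlighted.
#' @method autoplot ras_differential
#' @export
autoplot.ras_differential <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("log2 fold-change (%s / %s)",
                  attr(object, "group_A"), attr(object, "group_B")),
      y = "-log10 adjusted p-value",
      colour = sprintf("padj <= %g", attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
}
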