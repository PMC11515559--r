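#' Marker reactions per cluster
#'
#' Identifies, for each cluster, the reactions whose activity
#' distinguishes it from the remaining samples, with Welch two-sample
#' t-tests on the (adjusted, typically log-scale) activity values. Two
#' modes are available:
#'
#' * `"vs_rest"` (default): each cluster is tested against all other
#'   non-noise samples pooled;
#' * `"pairwise_max"`: each cluster is tested against every other cluster
#'   separately and the largest p-value is reported -- a marker is then
#'   only called when the reaction separates the cluster from *every*
#'   other cluster (the `findMarkers(pval.type = "all")` semantics).
#'
#' With exactly two clusters the two modes coincide. Noise samples
#' (label 0) are excluded throughout; clusters with fewer than two samples
#' are skipped with a warning. Reactions with zero variance in both
#' compared groups and equal means are reported with p = 1 and flagged.
#'
#' @param M Reaction x sample matrix (adjusted RAS, scaled or not).
#' @param labels Integer cluster labels aligned with the columns of `M`
#'   (0 = noise), or a `ras_embedding`.
#' @param mode `"vs_rest"` or `"pairwise_max"`.
#' @return A tibble of class `ras_markers` with columns `cluster`,
#'   `reaction_id`, `lfc` (mean difference cluster minus rest), `pvalue`,
#'   `fdr` (BH within cluster) and `zero_variance`, sorted by ascending
#'   p-value within each cluster.
#' @export
marker_reactions <- function(M, labels, mode = c("vs_rest", "pairwise_max")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(M))
  if (inherits(labels, "ras_embedding")) labels <- labels$cluster
  stopifnot(length(labels) == ncol(M))
  keep <- labels > 0
  cls <- sort(unique(labels[keep]))
  if (length(cls) < 2) {
    abort("Need at least two non-noise clusters.", class = "rasnet_data_error")
  }
  res <- list()
  for (g in cls) {
    idx_g <- which(labels == g)
    if (length(idx_g) < 2) {
      warn(sprintf("Cluster %d has fewer than 2 samples; skipped.", g),
           class = "rasnet_small_cluster")
      next
    }
    idx_rest <- which(keep & labels != g)
    if (length(idx_rest) < 2) {
      warn(sprintf("Cluster %d has fewer than 2 comparison samples; skipped.", g),
           class = "rasnet_small_cluster")
      next
    }
    base <- row_welch(M, idx_g, idx_rest)
    pv <- base$p
    if (mode == "pairwise_max") {
      for (h in setdiff(cls, g)) {
        idx_h <- which(labels == h)
        if (length(idx_h) < 2) next
        pv <- pmax(pv, row_welch(M, idx_g, idx_h)$p)
      }
    }
    tab <- tibble(
      cluster = g,
      reaction_id = rownames(M) %||% as.character(seq_len(nrow(M))),
      lfc = unname(base$diff),
      pvalue = unname(pv),
      fdr = unname(bh_adjust(pv)),
      zero_variance = unname(base$zero_var)
    )
    res[[length(res) + 1L]] <- arrange(tab, .data$pvalue)
  }
  if (length(res) == 0) {
    abort("No cluster comparison had at least 2 samples on both sides.",
          class = "rasnet_data_error")
  }
  out <- bind_rows(res)
  structure(out, class = c("ras_markers", class(out)), mode = mode)
}

# Vectorized Welch t-test of every row of M between two column index sets.
# Zero-variance rows with equal means get p = 1 (no evidence, flagged);
# zero-variance rows with different means get p = 0.
row_welch <- function(M, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- unclass(M)[, idx1, drop = FALSE]
  x2 <- unclass(M)[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  zero_var <- se2 == 0
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[zero_var] <- ifelse(m1[zero_var] == m2[zero_var], 1, 0)
  list(p = p, diff = m1 - m2, zero_var = zero_var)
}
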