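# Per-cell module scoring against the poor/better signatures, four-group
# assignment, and one-vs-rest differential expression.

#' Per-cell module score with expression-matched controls
#'
#' Genes are binned (`n_bins` equal-frequency bins) by their average
#' expression across cells. For every set gene, `n_ctrl` control genes are
#' sampled from its bin (excluding set genes; with replacement when the pool
#' is smaller than `n_ctrl`). The score of a cell is the mean expression of
#' the set genes minus the mean expression of the sampled control genes, so
#' a global additive shift of a cell cancels exactly. If excluding set genes
#' empties a bin's pool, the set gene serves as its own control (exact
#' cancellation), which makes the score identically zero when the set covers
#' all genes.
#'
#' @param cells genes x cells log-normalized expression matrix.
#' @param gene_set character vector; at least one member must be present.
#' @param n_bins number of average-expression bins (>= 2).
#' @param n_ctrl control genes drawn per set gene.
#' @param seed RNG seed for the control draw.
#' @return named per-cell numeric score vector.
#' @export
module_score <- function(cells, gene_set, n_bins = 24, n_ctrl = 100, seed = 1) {
  if (n_bins < 2) config_error("n_bins must be at least 2")
  set_genes <- intersect(gene_set, rownames(cells))
  if (!length(set_genes)) contract_error("no gene of the set is present")
  avg <- rowMeans(cells)
  # equal-frequency bins; ties split deterministically by rank order
  bins <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  names(bins) <- rownames(cells)

  ctrl <- character(0)
  with_seed(seed, {
    for (g in set_genes) {
      pool <- setdiff(names(bins)[bins == bins[g]], set_genes)
      if (!length(pool)) {
        ctrl <- c(ctrl, rep(g, n_ctrl))       # degenerate bin: self-control
      } else {
        ctrl <- c(ctrl, sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
      }
    }
  })
  set_mean <- colMeans(cells[set_genes, , drop = FALSE])
  ctrl_mean <- colMeans(cells[ctrl, , drop = FALSE])   # multiset of controls
  set_mean - ctrl_mean
}

#' Assign cells to four signature groups
#'
#' A cell is positive for a module when its score strictly exceeds the
#' module's cutoff (by default the mean of that module's scores across
#' cells; a fixed numeric cutoff may be supplied instead). Positivity for
#' both modules gives `"both"`, for one module its name, for neither
#' `"none"`.
#'
#' @param score_poor,score_better per-cell score vectors over the same cells.
#' @param cutoff_rule `"mean"` (per-module mean across cells) or a numeric
#'   vector of length 2 with fixed cutoffs (poor, better).
#' @return object of class `module_groups`: data.frame (cell, score_poor,
#'   score_better, group) with the cutoffs as an attribute.
#' @export
assign_four_groups <- function(score_poor, score_better, cutoff_rule = "mean") {
  if (length(score_poor) != length(score_better))
    contract_error("score vectors differ in length")
  cut <- if (identical(cutoff_rule, "mean"))
    c(poor = mean(score_poor), better = mean(score_better))
  else if (is.numeric(cutoff_rule) && length(cutoff_rule) == 2)
    c(poor = cutoff_rule[1], better = cutoff_rule[2])
  else config_error("cutoff_rule must be \"mean\" or two numeric cutoffs")
  pos_p <- score_poor > cut["poor"]
  pos_b <- score_better > cut["better"]
  group <- ifelse(pos_p & pos_b, "both",
                  ifelse(pos_p, "poor", ifelse(pos_b, "better", "none")))
  res <- data.frame(cell = names(score_poor), score_poor = score_poor,
                    score_better = score_better, group = group,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "cutoffs") <- cut
  class(res) <- c("module_groups", "data.frame")
  res
}

#' One-vs-rest differential expression across cell groups
#'
#' For each group with at least `min_cells` cells, every gene is tested by a
#' two-sided Wilcoxon rank-sum test of that group against all other cells
#' (exact distribution for combined n <= 25, normal approximation with
#' tie/continuity correction otherwise). p-values are Bonferroni-adjusted
#' across genes within each comparison.
#'
#' @param cells genes x cells expression matrix.
#' @param groups per-cell group labels.
#' @param genes genes to test (default: all).
#' @param min_cells minimum group size (smaller groups are skipped).
#' @return data.frame: group, gene, effect (mean difference group - rest),
#'   p, p_adj, significant; attribute `skipped_groups`.
#' @export
one_vs_rest_de <- function(cells, groups, genes = rownames(cells),
                           min_cells = 3) {
  if (length(groups) != ncol(cells))
    contract_error("one group label per cell is required")
  genes <- intersect(genes, rownames(cells))
  lev <- sort(unique(groups))
  sizes <- table(factor(groups, levels = lev))
  skipped <- names(sizes)[sizes < min_cells]
  if (length(skipped))
    warning(paste("groups skipped (too few cells):",
                  paste(skipped, collapse = ", ")), call. = FALSE)
  out <- list()
  for (g in setdiff(lev, skipped)) {
    in_g <- groups == g
    exact <- length(groups) <= 25
    p <- vapply(genes, function(gene) {
      x <- cells[gene, in_g]; y <- cells[gene, !in_g]
      if (sd(c(x, y)) == 0) return(1)
      suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    }, numeric(1))
    eff <- rowMeans(cells[genes, in_g, drop = FALSE]) -
      rowMeans(cells[genes, !in_g, drop = FALSE])
    out[[g]] <- data.frame(group = g, gene = genes, effect = unname(eff),
                           p = unname(p),
                           p_adj = unname(p.adjust(p, method = "bonferroni")),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (is.null(res)) res <- data.frame(group = character(0), gene = character(0),
                                      effect = numeric(0), p = numeric(0),
                                      p_adj = numeric(0))
  res$significant <- res$p_adj < 0.05
  attr(res, "skipped_groups") <- skipped
  res
}
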