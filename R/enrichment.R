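# Set-overlap statistics: Fisher tables, permutation nulls for
# protein-complex enrichment, alteration-frequency comparisons, and
# hypergeometric overlaps.

#' Two-by-two Fisher's exact test
#'
#' Two-tailed conditional hypergeometric p-value (sum of table probabilities
#' no larger than the observed one) with the sample odds ratio
#' `(a d) / (b c)`. Zero cells make the odds ratio 0 or infinite; these are
#' flagged rather than continuity-corrected.
#'
#' @param a,b,c,d nonnegative integer cell counts (row 1: a, b; row 2: c, d).
#' @return list `odds_ratio`, `p`, `flagged` (TRUE for degenerate OR).
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells %% 1 != 0))
    contract_error("cell counts must be nonnegative integers")
  if (sum(cells) == 0) contract_error("empty contingency table")
  or <- if (a * d == 0 && b * c == 0) NaN else if (b * c == 0) Inf
        else (a * d) / (b * c)
  p <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
  list(odds_ratio = or, p = p, flagged = !is.finite(or) || or == 0)
}

# Odds ratios for many complexes at once given a logical top-flag vector.
# membership: genes x complexes logical matrix.
complex_ors <- function(top, membership) {
  a <- colSums(membership & top)            # complex & top
  b <- colSums(membership & !top)           # complex & not top
  m <- colSums(membership)
  c_ <- sum(top) - a
  d <- length(top) - m - c_
  or <- (a * d) / (b * c_)
  or[a * d == 0] <- 0                       # includes 0/0
  or[b * c_ == 0 & a * d > 0] <- Inf
  or
}

#' Permutation test for protein-complex enrichment among top genes
#'
#' For each complex, the observed enrichment of top-flagged genes is the odds
#' ratio of the 2x2 table (complex membership x top flag) over the variable
#' gene universe. The null distribution comes from permuting the top flags;
#' the one-sided empirical p-value uses the plus-one rule
#' `(1 + #{null OR >= observed}) / (n_perm + 1)` (infinite ORs rank above all
#' finite ones). p-values are BH-adjusted across complexes.
#'
#' @param top_flags named logical vector over the gene universe.
#' @param membership named list: complex -> member genes, or a gene x complex
#'   logical matrix.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame: complex, a, b, c, d, odds_ratio, p, p_adj, enriched;
#'   complexes without members in the universe are skipped (attribute
#'   `skipped`).
#' @export
permutation_enrichment <- function(top_flags, membership, n_perm = 10000,
                                   seed = 1) {
  if (n_perm < 1) config_error("n_perm must be positive")
  genes <- names(top_flags)
  if (is.null(genes)) contract_error("top_flags must be named by gene")
  if (is.list(membership)) {
    mm <- vapply(membership, function(g) genes %in% g,
                 logical(length(genes)))
    rownames(mm) <- genes
  } else mm <- membership[genes, , drop = FALSE]
  sizes <- colSums(mm)
  skipped <- colnames(mm)[sizes == 0]
  if (length(skipped))
    warning(paste("complexes without members in the universe skipped:",
                  paste(skipped, collapse = ", ")), call. = FALSE)
  mm <- mm[, sizes > 0, drop = FALSE]

  obs <- complex_ors(top_flags, mm)
  a <- colSums(mm & top_flags); b <- colSums(mm & !top_flags)
  c_ <- sum(top_flags) - a; d <- length(top_flags) - a - b - c_

  exceed <- integer(ncol(mm))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      null_or <- complex_ors(sample(top_flags), mm)
      exceed <- exceed + (null_or >= obs)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  res <- data.frame(complex = colnames(mm), a = a, b = b, c = c_, d = d,
                    odds_ratio = obs, p = p,
                    p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$enriched <- res$p_adj < 0.05
  attr(res, "skipped") <- skipped
  res
}

#' Compare alteration frequencies between two clusters
#'
#' Genes altered in at least `min_fraction` of the tumors of either cluster
#' are tested by a two-tailed Fisher's exact test on altered/not x cluster;
#' p-values are BH-adjusted across the tested genes.
#'
#' @param alterations binary genes x samples matrix.
#' @param labels two-level cluster labels named by sample.
#' @param min_fraction minimum within-cluster alteration fraction.
#' @return data.frame: gene, f1, f2, p, p_adj (possibly zero rows).
#' @export
compare_alteration_frequencies <- function(alterations, labels,
                                           min_fraction = 0.10) {
  cl <- sort(unique(labels))
  if (length(cl) != 2) contract_error("exactly two clusters are required")
  alt <- alterations[, names(labels), drop = FALSE]
  if (!all(alt %in% c(0, 1))) contract_error("alteration matrix must be binary")
  in1 <- labels == cl[1]
  n1 <- sum(in1); n2 <- sum(!in1)
  a1 <- rowSums(alt[, in1, drop = FALSE])
  a2 <- rowSums(alt[, !in1, drop = FALSE])
  f1 <- a1 / n1; f2 <- a2 / n2
  keep <- f1 >= min_fraction | f2 >= min_fraction
  res <- data.frame(gene = rownames(alt)[keep], f1 = unname(f1[keep]),
                    f2 = unname(f2[keep]),
                    p = rep(NA_real_, sum(keep)),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- vapply(which(keep), function(i)
    fisher.test(matrix(c(a1[i], n1 - a1[i], a2[i], n2 - a2[i]), 2))$p.value,
    numeric(1))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail probability of observing at least the given overlap when sets
#' of the observed sizes are drawn from a common universe.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe_size size of the common universe.
#' @return p-value `P(X >= |A intersect B|)`.
#' @export
hypergeometric_overlap <- function(setA, setB, universe_size) {
  nA <- length(unique(setA)); nB <- length(unique(setB))
  if (nA > universe_size || nB > universe_size)
    contract_error("set larger than the universe")
  k <- length(intersect(setA, setB))
  if (k > min(nA, nB)) contract_error("overlap exceeds the smaller set")
  phyper(k - 1, nA, universe_size - nA, nB, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (clipped at 1, monotone in the raw p).
#' @param pvals p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    contract_error("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}
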