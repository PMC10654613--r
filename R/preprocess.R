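# Sample filtering, median-of-ratios normalization and variable-epifactor
# selection feeding the clustering stage.

#' Filter samples by tumor purity
#'
#' Keeps samples whose purity passes the threshold on ANY available purity
#' metric (columns of `clinical` whose names start with `purity`). Mirrors the
#' dual-metric rule used for high-purity cohort construction: a sample
#' qualifies if either estimate reaches the threshold.
#'
#' @param clinical clinical data.frame with a `sample_id` column and at least
#'   one `purity*` column.
#' @param purity_threshold minimum purity fraction (default 0.70).
#' @param min_cohort minimum cohort size below which the result is flagged.
#' @return character vector of retained sample ids, with attribute
#'   `undersized` (logical).
#' @export
filter_samples <- function(clinical, purity_threshold = 0.70, min_cohort = 70) {
  pur_cols <- grep("^purity", names(clinical), value = TRUE)
  if (!length(pur_cols)) contract_error("clinical table has no purity columns")
  pur <- as.matrix(clinical[, pur_cols, drop = FALSE])
  keep <- apply(pur >= purity_threshold, 1, any, na.rm = TRUE)
  ids <- clinical$sample_id[keep]
  undersized <- length(ids) < min_cohort
  if (undersized)
    warning(sprintf("only %d samples pass the purity filter (< %d)",
                    length(ids), min_cohort), call. = FALSE)
  structure(ids, undersized = undersized)
}

#' Median-of-ratios size factors
#'
#' Library-size normalization factors computed by the median-of-ratios
#' method: per gene, a geometric-mean reference over samples (genes with any
#' zero count are excluded from the reference); the factor of a sample is the
#' median over reference genes of `count / reference`. Delegates to
#' `DESeq2::estimateSizeFactorsForMatrix`.
#'
#' @param counts genes x samples count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  if (!any(rowSums(counts > 0) == ncol(counts)))
    numerical_error("no gene has nonzero counts in every sample")
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  names(sf) <- colnames(counts)
  sf
}

#' Log2 normalization of counts
#'
#' `log2(count / factor + pseudocount)` per entry; the default pseudocount of
#' 1 keeps zero counts at value 0.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample positive size factors (default from
#'   [size_factors()]).
#' @param pseudocount nonnegative shift before the log (default 1).
#' @return list of class `normalized_matrix` with `values` (log2 matrix) and
#'   `size_factors`.
#' @export
normalize_log2 <- function(counts, factors = size_factors(counts),
                           pseudocount = 1) {
  check_count_matrix(counts)
  if (length(factors) != ncol(counts))
    contract_error("one size factor per sample is required")
  if (any(factors <= 0)) contract_error("size factors must be positive")
  if (pseudocount < 0) contract_error("pseudocount must be nonnegative")
  values <- log2(sweep(counts, 2, factors, `/`) + pseudocount)
  structure(list(values = values, size_factors = factors),
            class = "normalized_matrix")
}

norm_values <- function(norm) {
  if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
}

#' Select variable epifactor genes by standard-deviation cutoff
#'
#' Restricts the normalized matrix to annotated epifactor genes and keeps
#' those whose per-gene standard deviation across samples exceeds a cutoff.
#' If no cutoff is given, one is chosen automatically on a grid of SD
#' quantiles (steps of 0.005) so that the selected count lands in
#' `target_range` (the conventional 500-600 window); if no grid point
#' achieves that, the closest achievable count is returned and flagged.
#'
#' @param norm a `normalized_matrix` or plain log2 matrix.
#' @param annotation epifactor annotation data.frame (`gene`, `is_epifactor`).
#' @param target_range integer interval for the automatic search.
#' @param sd_cutoff optional explicit cutoff; disables the search.
#' @return list with `genes` (character vector, SD-sorted descending), `sds`
#'   (their SDs), `cutoff`, and `in_range` flag.
#' @export
select_variable_epifactors <- function(norm, annotation,
                                       target_range = c(500, 600),
                                       sd_cutoff = NULL) {
  values <- norm_values(norm)
  epi <- annotation$gene[as.logical(annotation$is_epifactor)]
  epi <- intersect(epi, rownames(values))
  if (!length(epi))
    contract_error("no annotated epifactor gene is present in the matrix")
  sds <- apply(values[epi, , drop = FALSE], 1, sd)

  pick <- function(cut) epi[sds > cut]
  if (!is.null(sd_cutoff)) {
    genes <- pick(sd_cutoff)
    if (!length(genes))
      warning("no epifactor gene exceeds the SD cutoff", call. = FALSE)
    ord <- order(-sds[genes])
    return(list(genes = genes[ord], sds = sds[genes][ord],
                cutoff = sd_cutoff,
                in_range = length(genes) >= target_range[1] &&
                  length(genes) <= target_range[2]))
  }
  grid <- unique(quantile(sds, probs = seq(0, 1, by = 0.005), names = FALSE,
                          type = 7))
  counts_at <- vapply(grid, function(g) length(pick(g)), integer(1))
  in_range <- counts_at >= target_range[1] & counts_at <= target_range[2]
  if (any(in_range)) {
    # among achievable cutoffs take the largest (most stringent) in range
    idx <- max(which(in_range))
  } else {
    dist_to <- pmax(target_range[1] - counts_at, counts_at - target_range[2], 0)
    idx <- which.min(dist_to)
    warning(sprintf("target range [%d, %d] unreachable; closest count is %d",
                    target_range[1], target_range[2], counts_at[idx]),
            call. = FALSE)
  }
  cutoff <- grid[idx]
  genes <- pick(cutoff)
  list(genes = genes[order(-sds[genes])], sds = sds[genes][order(-sds[genes])],
       cutoff = cutoff, in_range = any(in_range))
}
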