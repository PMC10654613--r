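# Single-sample gene-set scoring (weighted KS running sum) and higher-score
# outcome classification of validation samples.

# Running-sum enrichment score for one sample given average-tie ranks.
ss_score_one <- function(ranks, in_set, weight_exponent) {
  ord <- order(ranks, decreasing = TRUE)
  inset_ord <- in_set[ord]
  w <- ranks[ord]^weight_exponent
  p_in <- cumsum(ifelse(inset_ord, w, 0)) / sum(w[inset_ord])
  n_out <- sum(!in_set)
  p_out <- cumsum(!inset_ord) / n_out
  sum(p_in - p_out)
}

#' Single-sample enrichment score for a gene set
#'
#' Rank-based single-sample enrichment in the weighted Kolmogorov-Smirnov
#' style: per sample, genes are ranked by expression (average ranks for
#' ties); the running sum steps up by `rank^weight_exponent` (normalized) at
#' set genes and down uniformly at non-set genes, and the score is the sum of
#' the running-sum deviations. Depends only on within-sample ranks, so it is
#' invariant to any strictly monotone transform of a sample's values.
#'
#' @param norm `normalized_matrix` or expression matrix (genes x samples).
#' @param gene_set character vector; at least one member must be present.
#' @param weight_exponent rank weight (default 0.25).
#' @return named per-sample numeric score vector.
#' @export
ss_enrichment <- function(norm, gene_set, weight_exponent = 0.25) {
  values <- norm_values(norm)
  in_set <- rownames(values) %in% gene_set
  if (!any(in_set)) contract_error("no gene of the set is present")
  if (all(in_set)) contract_error("the set covers the whole matrix")
  apply(values, 2, function(x)
    ss_score_one(rank(x, ties.method = "average"), in_set, weight_exponent))
}

#' Classify samples by competing signature scores
#'
#' Scores every sample for the poor-outcome and better-outcome signatures and
#' assigns the label of the higher score; exact ties are left unclassified
#' (`NA`) and flagged.
#'
#' @param norm `normalized_matrix` or expression matrix.
#' @param sig_poor,sig_better gene sets (character vectors).
#' @param weight_exponent passed to [ss_enrichment()].
#' @return data.frame: sample, score_poor, score_better, call
#'   ("poor"/"better"/NA).
#' @export
classify_by_signatures <- function(norm, sig_poor, sig_better,
                                   weight_exponent = 0.25) {
  sp <- ss_enrichment(norm, sig_poor, weight_exponent)
  sb <- ss_enrichment(norm, sig_better, weight_exponent)
  call <- ifelse(sp > sb, "poor", ifelse(sb > sp, "better", NA))
  if (anyNA(call))
    warning(sprintf("%d sample(s) tied and left unclassified", sum(is.na(call))),
            call. = FALSE)
  data.frame(sample = names(sp), score_poor = sp, score_better = sb,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}
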