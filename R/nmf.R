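# Consensus NMF stratification: factorization, consensus clustering,
# validation metrics, rank selection and signature-gene extraction.

#' Non-negative matrix factorization by KL multiplicative updates
#'
#' Factorizes a nonnegative matrix `V` (genes x samples) as `V ~ W H`,
#' minimizing the generalized Kullback-Leibler divergence `D(V || WH)` with
#' the classic multiplicative updates. Factors are initialized uniformly at
#' random from the seed; the objective trace is non-increasing by
#' construction.
#'
#' @param V nonnegative numeric matrix.
#' @param k factorization rank, `k < min(dim(V))`.
#' @param seed RNG seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-change convergence tolerance.
#' @return object of class `nmf_fit`: `W` (genes x k), `H` (k x samples),
#'   `objective_trace`, `seed`, `k`.
#' @export
nmf_factorize <- function(V, k, seed = 1, max_iter = 500, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) contract_error("V has negative entries; NMF needs V >= 0")
  if (k >= min(dim(V)) || k < 1)
    contract_error("rank k must satisfy 1 <= k < min(dim(V))")
  scale0 <- sqrt(mean(V) / k)
  init <- with_seed(seed, list(
    W = matrix(runif(nrow(V) * k, 1e-4, 1), nrow(V), k) * scale0,
    H = matrix(runif(k * ncol(V), 1e-4, 1), k, ncol(V)) * scale0))
  fit <- .nmf_kl_cpp(V, init$W, init$H, as.integer(max_iter), tol)
  dimnames(fit$W) <- list(rownames(V), paste0("k", seq_len(k)))
  dimnames(fit$H) <- list(paste0("k", seq_len(k)), colnames(V))
  structure(list(W = fit$W, H = fit$H, objective_trace = fit$trace,
                 seed = seed, k = k), class = "nmf_fit")
}

#' Cluster labels of one NMF run
#'
#' A sample belongs to the metagene (row of `H`) with the largest
#' coefficient in its column; ties go to the lowest index.
#' @param fit an `nmf_fit`.
#' @return integer vector of cluster labels named by sample.
#' @export
nmf_cluster_labels <- function(fit) {
  labs <- apply(fit$H, 2, which.max)
  setNames(as.integer(labs), colnames(fit$H))
}

#' Consensus NMF clustering
#'
#' Repeats the factorization from `n_runs` seeded restarts, records how often
#' each sample pair lands in the same argmax-metagene cluster, and derives
#' final labels from average-linkage hierarchical clustering of
#' `1 - consensus` cut at `k`. Cophenetic, silhouette and connectivity
#' validation metrics are attached.
#'
#' @param V nonnegative genes x samples matrix.
#' @param k rank / number of clusters.
#' @param n_runs number of seeded NMF restarts (>= 2).
#' @param seed base seed; run r uses `seed + r`.
#' @param metric_space `"expression"` (default) computes silhouette and
#'   connectivity on Euclidean distances between sample expression profiles;
#'   `"consensus"` uses `1 - consensus` as the distance.
#' @param L neighbor count for the connectivity metric.
#' @param ... passed to [nmf_factorize()].
#' @return object of class `consensus_result`: `k`, `consensus`, `labels`,
#'   `n_runs`, `metrics` (cophenetic, silhouette, connectivity), and the
#'   best-objective `fit`.
#' @export
consensus_cluster <- function(V, k, n_runs = 30, seed = 1,
                              metric_space = c("expression", "consensus"),
                              L = 10, ...) {
  metric_space <- match.arg(metric_space)
  if (n_runs < 2) config_error("n_runs must be at least 2")
  V <- as.matrix(V)
  n <- ncol(V)
  co <- matrix(0, n, n)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(V, k, seed = seed + r, ...)
    labs <- nmf_cluster_labels(fit)
    co <- co + outer(labs, labs, `==`)
    if (is.null(best) || tail(fit$objective_trace, 1) <
        tail(best$objective_trace, 1)) best <- fit
  }
  consensus <- co / n_runs
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(V), colnames(V))

  hc <- hclust(as.dist(1 - consensus), method = "average")
  labels <- setNames(as.integer(cutree(hc, k = k)), colnames(V))

  dmat <- if (metric_space == "expression") dist(t(V)) else
    as.dist(1 - consensus)
  metrics <- list(
    cophenetic = cophenetic_coefficient(consensus),
    silhouette = silhouette_score(dmat, labels),
    connectivity = connectivity(dmat, labels, L = min(L, n - 1)))
  structure(list(k = k, consensus = consensus, labels = labels,
                 n_runs = n_runs, metrics = metrics, fit = best,
                 dendrogram = hc),
            class = "consensus_result")
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the off-diagonal consensus dissimilarities
#' `1 - consensus` and the cophenetic distances of their average-linkage
#' dendrogram. Values near 1 indicate stable co-clustering.
#'
#' @param consensus symmetric sample x sample matrix with unit diagonal.
#' @return correlation in [-1, 1]; `NA` with attribute `degenerate = TRUE`
#'   when all dissimilarities are equal.
#' @export
cophenetic_coefficient <- function(consensus) {
  if (!isTRUE(all.equal(consensus, t(consensus), tolerance = 1e-8)) ||
      any(abs(diag(consensus) - 1) > 1e-8))
    contract_error("consensus must be symmetric with unit diagonal")
  d <- as.dist(1 - consensus)
  if (sd(d) < 1e-12) {
    warning("constant consensus dissimilarities; cophenetic undefined",
            call. = FALSE)
    return(structure(NA_real_, degenerate = TRUE))
  }
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) < 1e-12) {
    # ultrametric collapsed to a single height: correlation undefined
    warning("degenerate dendrogram heights; cophenetic undefined", call. = FALSE)
    return(structure(NA_real_, degenerate = TRUE))
  }
  cor(d, cd)
}

#' Mean silhouette width
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` on Euclidean (or given)
#' distances, averaged over samples; singleton clusters contribute 0.
#'
#' @param data samples x features matrix, or a `dist` object.
#' @param labels cluster labels (>= 2 nonempty clusters).
#' @return mean silhouette width in [-1, 1].
#' @export
silhouette_score <- function(data, labels) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2)
    contract_error("silhouette needs at least two clusters")
  d <- if (inherits(data, "dist")) data else dist(data)
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Connectivity of a clustering
#'
#' For each sample, its `L` nearest neighbors are inspected in order; the
#' j-th neighbor adds a penalty `1/j` when it carries a different cluster
#' label. Lower values indicate better-connected clusters. Distance ties are
#' broken by sample index for determinism.
#'
#' @param data samples x features matrix, or a `dist` object.
#' @param labels cluster labels.
#' @param L number of nearest neighbors to inspect (`1 <= L <= n - 1`).
#' @return nonnegative penalty sum.
#' @export
connectivity <- function(data, labels, L = 10) {
  d <- if (inherits(data, "dist")) as.matrix(data) else as.matrix(dist(data))
  n <- nrow(d)
  if (L < 1 || L >= n) contract_error("L must satisfy 1 <= L <= n - 1")
  labels <- as.integer(as.factor(labels))
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])   # ties broken by sample index
    nn <- (seq_len(n)[-i])[ord][seq_len(L)]
    total <- total + sum((labels[nn] != labels[i]) / seq_len(L))
  }
  total
}

#' Select the clustering rank by majority vote of validation metrics
#'
#' Each metric ranks the candidate `k`s (cophenetic and silhouette: higher is
#' better; connectivity: lower is better); the chosen rank is the majority
#' winner, with ties resolved toward the smallest `k`.
#'
#' @param metric_table data.frame with columns `k`, `cophenetic`,
#'   `silhouette`, `connectivity` (one row per candidate rank).
#' @return the chosen rank (integer).
#' @export
select_rank <- function(metric_table) {
  need <- c("k", "cophenetic", "silhouette", "connectivity")
  if (!all(need %in% names(metric_table)))
    contract_error("metric_table must contain k and all three metrics")
  if (nrow(metric_table) < 2)
    contract_error("at least two candidate ranks are required")
  if (anyNA(metric_table[need]))
    contract_error("missing metric values")
  ks <- metric_table$k
  winners <- c(ks[which.max(metric_table$cophenetic)],
               ks[which.max(metric_table$silhouette)],
               ks[which.min(metric_table$connectivity)])
  tab <- table(winners)
  best <- as.integer(names(tab)[tab == max(tab)])
  min(best)
}

#' Kim-Park metagene specificity scores
#'
#' For gene i with normalized basis loadings `p_iq = W_iq / sum_q W_iq`, the
#' score is `1 + (1 / log2 k) * sum_q p_iq log2 p_iq` (with `0 log 0 = 0`):
#' 1 for a gene loading on a single metagene, 0 for a uniform gene.
#'
#' @param W nonnegative basis matrix with >= 2 columns.
#' @return numeric vector of scores in [0, 1]; `NA` for all-zero rows.
#' @export
kim_park_score <- function(W) {
  k <- ncol(W)
  if (k < 2) contract_error("Kim-Park scores need at least 2 metagenes")
  rs <- rowSums(W)
  p <- W / ifelse(rs > 0, rs, NA)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  score <- 1 + rowSums(plogp) / log2(k)
  score[rs == 0] <- NA
  score
}

#' Extract signature (top NMF) genes from a basis matrix
#'
#' Selects genes with Kim-Park score above `mean + 3 sd` of all scores AND
#' maximum basis loading above the median of all entries of `W`; each
#' selected gene is assigned to its argmax metagene (ties to the lowest
#' index).
#'
#' @param W nonnegative genes x k basis matrix (k >= 2); all-zero rows are
#'   skipped.
#' @return object of class `signature_set`: per-cluster gene lists with
#'   scores, the full score table, and an empty `outcome_label`.
#' @export
extract_top_genes <- function(W) {
  if (ncol(W) < 2) contract_error("signature extraction needs k >= 2")
  score <- kim_park_score(W)
  usable <- !is.na(score)
  thr <- mean(score[usable]) + 3 * sd(score[usable])
  big <- apply(W, 1, max) > median(W)
  sel <- usable & score > thr & big
  assign <- apply(W, 1, which.max)
  table <- data.frame(gene = rownames(W), score = score, cluster = assign,
                      selected = sel, stringsAsFactors = FALSE,
                      row.names = NULL)
  sets <- lapply(seq_len(ncol(W)), function(q) {
    g <- rownames(W)[sel & assign == q]
    g[order(-score[match(g, rownames(W))])]
  })
  names(sets) <- paste0("cluster", seq_len(ncol(W)))
  structure(list(signatures = sets, table = table, threshold = thr,
                 outcome_label = NULL),
            class = "signature_set")
}

#' Label clusters by survival outcome
#'
#' In a two-cluster solution, the cluster with the lower Kaplan-Meier
#' survival at the cohort's median follow-up time is labeled `"poor"`, the
#' other `"better"`. Ties fall back to the sign of the log hazard ratio.
#'
#' @param labels two-level cluster labels named by sample.
#' @param clinical clinical table with `sample_id`, `time_<endpoint>`,
#'   `event_<endpoint>` columns.
#' @param endpoint survival endpoint suffix (default `"pfi"`).
#' @return named character vector mapping cluster id -> "poor"/"better", or
#'   `NULL` with a warning when no events allow labeling.
#' @export
label_clusters_by_outcome <- function(labels, clinical, endpoint = "pfi") {
  cl <- sort(unique(labels))
  if (length(cl) != 2) contract_error("outcome labeling expects two clusters")
  idx <- match(names(labels), clinical$sample_id)
  time <- clinical[[paste0("time_", endpoint)]][idx]
  event <- clinical[[paste0("event_", endpoint)]][idx]
  if (sum(event) == 0) {
    warning("no events in either cluster; clusters left unlabeled", call. = FALSE)
    return(NULL)
  }
  t_ref <- median(time)
  surv_at <- vapply(cl, function(g) {
    km <- km_estimate(time[labels == g], event[labels == g])
    s <- c(1, km$survival)[findInterval(t_ref, c(0, km$time))]
    s
  }, numeric(1))
  if (abs(diff(surv_at)) > 1e-12) {
    poor <- cl[which.min(surv_at)]
  } else {
    cf <- survival::coxph(survival::Surv(time, event) ~ I(labels == cl[2]))
    if (abs(coef(cf)) < 1e-12) {
      warning("indistinguishable survival; clusters left unlabeled",
              call. = FALSE)
      return(NULL)
    }
    poor <- if (coef(cf) > 0) cl[2] else cl[1]
  }
  out <- setNames(ifelse(cl == poor, "poor", "better"), cl)
  out
}

#' @exportS3Method base::print
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus NMF result: k = %d, %d samples, %d runs\n",
              x$k, ncol(x$consensus), x$n_runs))
  cat(sprintf("  cophenetic = %.3f, silhouette = %.3f, connectivity = %.2f\n",
              x$metrics$cophenetic, x$metrics$silhouette,
              x$metrics$connectivity))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @exportS3Method base::print
print.signature_set <- function(x, ...) {
  sizes <- vapply(x$signatures, length, integer(1))
  cat("Signature set:",
      paste(sprintf("%s (%d genes)", names(sizes), sizes), collapse = ", "),
      "\n")
  if (!is.null(x$outcome_label))
    cat("  outcome labels:",
        paste(names(x$outcome_label), x$outcome_label, sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}
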