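# Cluster-level and gene-level survival analysis. The product-limit
# estimator, Mantel-Cox test and Cox model are delegated to the survival
# package (Efron ties); the maximally selected cutpoint, meta-PCNA covariate
# and prognostic bookkeeping are implemented here.

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame (`time`, `survival`, `n_at_risk`, `n_event`) with one
#'   row per distinct observed time.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) contract_error("empty survival input")
  if (any(times <= 0)) contract_error("times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, survival = fit$surv, n_at_risk = fit$n.risk,
             n_event = fit$n.event)
}

#' Log-rank (Mantel-Cox) test
#'
#' @param group_labels group membership (>= 2 nonempty groups).
#' @param times positive follow-up times.
#' @param events event indicators.
#' @return list `chi2`, `df` (groups - 1), `p`, and `flagged` when no events
#'   occurred (then `p = 1`).
#' @export
logrank_test <- function(group_labels, times, events) {
  g <- as.factor(group_labels)
  if (any(table(g) == 0) || nlevels(g) < 2)
    contract_error("log-rank needs at least two nonempty groups")
  if (sum(events) == 0) {
    warning("no events; log-rank undefined, returning p = 1", call. = FALSE)
    return(list(chi2 = 0, df = nlevels(g) - 1L, p = 1, flagged = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE), flagged = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Efron partial likelihood maximized by Newton-Raphson (via
#' `survival::coxph`). Monotone-likelihood (perfect separation) is detected
#' through diverging coefficients / exploded standard errors and flagged as
#' non-converged.
#'
#' @param design data.frame or matrix of covariates (no constant columns).
#' @param times positive follow-up times.
#' @param events event indicators.
#' @param ties tie-handling method (default `"efron"`).
#' @return object of class `cox_fit`: `coefficients` table (coef, se, HR,
#'   CI bounds, Wald p), `loglik`, `iter`, `converged`.
#' @export
cox_fit <- function(design, times, events, ties = "efron") {
  design <- as.data.frame(design)
  nvar <- vapply(design, function(x) length(unique(x)), integer(1))
  if (any(nvar <= 1))
    contract_error(paste("constant covariate:",
                         paste(names(design)[nvar <= 1], collapse = ", ")))
  if (nrow(design) <= ncol(design))
    contract_error("more covariates than observations")
  dat <- cbind(.time = times, .event = events, design)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 25)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite|out of iterations",
                conditionMessage(w))) warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  se <- co[, "se(coef)"]
  beta <- co[, "coef"]
  tab <- data.frame(
    term = rownames(co), coef = beta, se = se, hr = exp(beta),
    hr_lo = exp(beta - 1.96 * se), hr_hi = exp(beta + 1.96 * se),
    p = co[, "Pr(>|z|)"], row.names = NULL, stringsAsFactors = FALSE)
  diverged <- any(!is.finite(beta)) || any(abs(beta) > 15) || any(se > 100)
  converged <- !warned && !diverged
  structure(list(coefficients = tab, loglik = fit$loglik[2], iter = fit$iter,
                 converged = converged, fit = fit),
            class = "cox_fit")
}

#' @exportS3Method base::print
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s)%s\n",
              if (x$converged) "converged" else "NOT CONVERGED - flagged",
              sprintf(", partial loglik %.2f", x$loglik)))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Compare clusters by survival across endpoints
#'
#' For each endpoint (PFI, DSS, OS present in the clinical table) computes
#' the log-rank test between clusters and a covariate-adjusted Cox model for
#' the cluster indicator. The adjustment set is swappable (age + sex by
#' default; purity, stromal/leukocyte fractions, stage/grade or alteration
#' flags can be added as columns of the clinical table).
#'
#' @param labels cluster labels named by sample.
#' @param clinical clinical table (`sample_id`, `time_*`, `event_*`, and the
#'   adjustment columns).
#' @param adjust_for character vector of clinical columns to adjust for.
#' @param endpoints endpoint suffixes to analyze.
#' @return named list per endpoint: `logrank` and `cox` (a `cox_fit`); the
#'   cluster term is `cluster2`. Collinear adjustment covariates are dropped
#'   with a flag.
#' @export
compare_clusters <- function(labels, clinical, adjust_for = c("age", "sex"),
                             endpoints = c("pfi", "dss", "os")) {
  idx <- match(names(labels), clinical$sample_id)
  if (anyNA(idx)) contract_error("labels contain samples absent from clinical")
  cl <- clinical[idx, , drop = FALSE]
  cluster2 <- as.integer(labels == sort(unique(labels))[2])
  out <- list()
  for (ep in endpoints) {
    tcol <- paste0("time_", ep); ecol <- paste0("event_", ep)
    if (!tcol %in% names(cl)) next
    design <- data.frame(cluster2 = cluster2)
    dropped <- character()
    for (v in adjust_for) {
      x <- cl[[v]]
      xn <- if (is.numeric(x)) x else as.integer(as.factor(x))
      if (length(unique(xn)) < 2 ||
          abs(cor(xn, cluster2)) > 1 - 1e-10) {
        dropped <- c(dropped, v)
      } else design[[v]] <- x
    }
    if (length(dropped))
      warning(paste("collinear/constant adjustment covariates dropped:",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    fit <- cox_fit(design, cl[[tcol]], cl[[ecol]])
    out[[ep]] <- list(
      logrank = logrank_test(labels, cl[[tcol]], cl[[ecol]]),
      cox = fit,
      cluster_p = fit$coefficients$p[fit$coefficients$term == "cluster2"],
      dropped_covariates = dropped)
  }
  out
}

# Risk-table structures shared by every gene of a screen: at-risk and
# event-indicator matrices over the distinct event times.
logrank_precompute <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  at_risk <- outer(times, ut, `>=`)                   # n x J
  died <- outer(times, ut, `==`) & (events == 1)      # n x J
  d <- colSums(died)
  n_r <- colSums(at_risk)
  list(at_risk = at_risk, died = died, d = d, n_r = n_r, n = length(times))
}

# Standardized two-group log-rank statistic (O - E) / sqrt(V) for a binary
# grouping (TRUE = "high"), from the hypergeometric risk-table moments.
logrank_z <- function(in_high, times, events,
                      pre = logrank_precompute(times, events)) {
  n1 <- colSums(pre$at_risk & in_high)
  d1 <- colSums(pre$died & in_high)
  frac <- n1 / pre$n_r
  O <- sum(d1)
  E <- sum(pre$d * frac)
  keep <- pre$n_r > 1
  V <- sum((pre$d * frac * (1 - frac) *
              (pre$n_r - pre$d) / (pre$n_r - 1))[keep])
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

# Log-rank z for every admissible prefix size m ("high" = the m largest
# expression values) in one pass: cumulative sums down the
# expression-descending sample order give the high-group risk counts for all
# cutpoints simultaneously.
cutpoint_scan <- function(expression, pre) {
  ord <- order(expression, decreasing = TRUE)
  N1 <- apply(pre$at_risk[ord, , drop = FALSE], 2, cumsum)  # m x J
  D1 <- apply(pre$died[ord, , drop = FALSE], 2, cumsum)
  frac <- sweep(N1, 2, pre$n_r, `/`)
  O <- rowSums(D1)
  E <- as.vector(frac %*% pre$d)
  vterm <- sweep(frac * (1 - frac), 2,
                 pre$d * (pre$n_r - pre$d) / pmax(pre$n_r - 1, 1), `*`)
  vterm[, pre$n_r <= 1] <- 0
  V <- rowSums(vterm)
  z <- ifelse(V > 0, (O - E) / sqrt(V), 0)
  z       # z[m] for high group = top-m samples by expression
}

#' Optimal expression cutpoint by maximally selected log-rank statistic
#'
#' Scans candidate cutpoints that leave at least `minprop` of samples on each
#' side and picks the one maximizing the absolute standardized log-rank
#' statistic between the resulting high/low groups (the maximally selected
#' rank statistic approach used for per-gene dichotomization). Ties are
#' broken toward the lower cutpoint.
#'
#' @param expression per-sample expression values (non-constant).
#' @param times positive follow-up times.
#' @param events event indicators.
#' @param minprop minimum fraction of samples per side, in (0, 0.5).
#' @param pre precomputed risk-table structures (internal; lets a screen
#'   share them across genes).
#' @return list `cutpoint`, `statistic` (signed z at the optimum), `groups`
#'   (factor `"low"`/`"high"`).
#' @export
optimal_cutpoint <- function(expression, times, events, minprop = 0.1,
                             pre = logrank_precompute(times, events)) {
  if (sd(expression) == 0) contract_error("constant expression; no cutpoint")
  if (minprop <= 0 || minprop >= 0.5)
    contract_error("minprop must lie in (0, 0.5)")
  n <- length(expression)
  z_all <- cutpoint_scan(expression, pre)
  # candidate cutpoints are observed values; "high" = expression > cutpoint.
  # Admissible when both sides keep >= ceil(minprop * n) samples.
  vals <- sort(unique(expression))
  m_of <- n - findInterval(vals, sort(expression))   # high-group size per value
  side_min <- max(1L, ceiling(minprop * n))
  ok <- m_of >= side_min & (n - m_of) >= side_min
  if (!any(ok)) numerical_error("no admissible cutpoint")
  vals <- vals[ok]; m_of <- m_of[ok]
  zs <- z_all[m_of]
  best <- which(abs(zs) == max(abs(zs)))[1]   # ties -> lower cutpoint
  groups <- factor(ifelse(expression > vals[best], "high", "low"),
                   levels = c("low", "high"))
  list(cutpoint = vals[best], statistic = zs[best], groups = groups)
}

#' Meta-PCNA proliferation signature and per-sample score
#'
#' The proliferation signature is the top fraction (default 1%) of genes
#' whose expression correlates most strongly (Pearson) with the anchor gene
#' PCNA; the per-sample score is the median of the signature genes' log2
#' normalized values, usable as a Cox adjustment covariate.
#'
#' @param norm `normalized_matrix` or log2 matrix.
#' @param anchor_gene anchor gene id (default `"PCNA"`).
#' @param top_frac fraction of genes (excluding the anchor) in the signature.
#' @return list `signature` (gene ids), `score` (named per-sample vector),
#'   `correlations`.
#' @export
meta_pcna <- function(norm, anchor_gene = "PCNA", top_frac = 0.01) {
  values <- norm_values(norm)
  if (!anchor_gene %in% rownames(values))
    contract_error(paste("anchor gene", anchor_gene, "absent"))
  anchor <- values[anchor_gene, ]
  if (sd(anchor) == 0) contract_error("anchor gene expression is constant")
  others <- values[setdiff(rownames(values), anchor_gene), , drop = FALSE]
  cors <- as.vector(cor(t(others), anchor))
  names(cors) <- rownames(others)
  n_top <- ceiling(top_frac * nrow(others))
  sig <- names(sort(cors, decreasing = TRUE))[seq_len(n_top)]
  score <- apply(values[sig, , drop = FALSE], 2, median)
  list(signature = sig, score = score, correlations = cors)
}

#' Per-gene prognostic screen with optimal-cutpoint dichotomization
#'
#' For every variable gene: dichotomize expression at the optimal cutpoint,
#' fit a Cox model with the high/low indicator plus adjustment covariates
#' (optionally including a `meta_pcna` score column of `clinical`), record
#' the direction ("poor-with-high" when the high-expression group has
#' HR > 1), and Benjamini-Hochberg-adjust the Wald p-values across genes.
#' Genes supplied in `genes` but not in `variable_genes` are reported as not
#' prognostic with reason `"non-variable"`.
#'
#' @param norm `normalized_matrix` or log2 matrix.
#' @param clinical clinical table.
#' @param genes genes to report (default: all `variable_genes`).
#' @param variable_genes genes that passed the variability filter.
#' @param adjust_for clinical columns used as Cox adjustment covariates.
#' @param endpoint endpoint suffix (default `"pfi"`).
#' @param alpha FDR level for the prognostic flag.
#' @param minprop cutpoint admissibility fraction.
#' @return data.frame of class `prognostic_table`: gene, cutpoint, group
#'   sizes, direction, p, p_adj, prognostic, reason.
#' @export
prognostic_screen <- function(norm, clinical, genes = NULL,
                              variable_genes = NULL,
                              adjust_for = c("age", "sex"),
                              endpoint = "pfi", alpha = 0.05, minprop = 0.1) {
  values <- norm_values(norm)
  if (is.null(variable_genes)) variable_genes <- rownames(values)
  if (is.null(genes)) genes <- variable_genes
  idx <- match(colnames(values), clinical$sample_id)
  if (anyNA(idx)) contract_error("matrix samples absent from clinical table")
  cl <- clinical[idx, , drop = FALSE]
  time <- cl[[paste0("time_", endpoint)]]
  event <- cl[[paste0("event_", endpoint)]]
  pre <- logrank_precompute(time, event)

  rows <- lapply(genes, function(g) {
    base <- data.frame(gene = g, cutpoint = NA_real_, n_low = NA_integer_,
                       n_high = NA_integer_, direction = NA_character_,
                       p = NA_real_, stringsAsFactors = FALSE)
    if (!g %in% variable_genes || !g %in% rownames(values) ||
        sd(values[g, ]) == 0) {
      base$reason <- "non-variable"
      return(base)
    }
    cp <- optimal_cutpoint(values[g, ], time, event, minprop = minprop,
                           pre = pre)
    design <- data.frame(high = as.integer(cp$groups == "high"))
    for (v in adjust_for) design[[v]] <- cl[[v]]
    fit <- tryCatch(cox_fit(design, time, event), error = function(e) NULL)
    if (is.null(fit)) { base$reason <- "cox-failed"; return(base) }
    co <- fit$coefficients[fit$coefficients$term == "high", ]
    base$cutpoint <- cp$cutpoint
    base$n_low <- sum(cp$groups == "low")
    base$n_high <- sum(cp$groups == "high")
    base$direction <- if (co$coef > 0) "poor-with-high" else "poor-with-low"
    base$p <- co$p
    base$reason <- if (fit$converged) "tested" else "not-converged"
    base
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  tested <- res$reason == "tested"
  res$p_adj[tested] <- p.adjust(res$p[tested], method = "BH")
  res$prognostic <- !is.na(res$p_adj) & res$p_adj < alpha
  class(res) <- c("prognostic_table", "data.frame")
  res
}

#' Prognostic residuals across cohorts
#'
#' For each gene, counts the cohorts where its high expression is
#' poor-prognostic (N) and where its low expression is poor-prognostic (M);
#' the prognostic residual is N - M. Per requested grouping (all genes, or
#' by annotation `category`, `subrole`, `mark`) the genes with positive and
#' negative residuals are counted and compared by a two-sided exact sign
#' test. Genes prognostic nowhere (N = M = 0) are excluded from the counts.
#'
#' @param tables list of `prognostic_table`s, one per cohort (>= 2).
#' @param annotation epifactor annotation data.frame.
#' @param groupings subset of `c("all", "category", "subrole", "mark")`.
#' @return list with `residuals` (per-gene data.frame: gene, N, M, residual)
#'   and `groups` (per-grouping level: n_positive, n_negative, sign-test p).
#' @export
prognostic_residuals <- function(tables, annotation,
                                 groupings = c("all", "category")) {
  if (length(tables) < 2) contract_error("at least two cohorts are required")
  allowed <- c("all", "category", "subrole", "mark")
  if (!all(groupings %in% allowed))
    contract_error(paste("unknown grouping key:",
                         paste(setdiff(groupings, allowed), collapse = ", ")))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  N <- M <- setNames(integer(length(genes)), genes)
  for (tb in tables) {
    pr <- tb[tb$prognostic, , drop = FALSE]
    hi <- pr$gene[pr$direction == "poor-with-high"]
    lo <- pr$gene[pr$direction == "poor-with-low"]
    N[hi] <- N[hi] + 1L
    M[lo] <- M[lo] + 1L
  }
  resid <- data.frame(gene = genes, N = unname(N), M = unname(M),
                      residual = unname(N - M), stringsAsFactors = FALSE)
  informative <- resid[resid$N + resid$M > 0, , drop = FALSE]

  sign_row <- function(sub, level) {
    pos <- sum(sub$residual > 0); neg <- sum(sub$residual < 0)
    p <- if (pos + neg > 0) binom.test(pos, pos + neg, 0.5)$p.value else NA_real_
    data.frame(group = level, n_positive = pos, n_negative = neg, p = p,
               stringsAsFactors = FALSE)
  }
  groups <- list()
  for (grp in groupings) {
    if (grp == "all") {
      groups[["all"]] <- sign_row(informative, "all")
    } else {
      key <- annotation[[grp]][match(informative$gene, annotation$gene)]
      for (lev in sort(unique(stats::na.omit(key))))
        groups[[paste(grp, lev, sep = ":")]] <-
          sign_row(informative[!is.na(key) & key == lev, , drop = FALSE],
                   paste(grp, lev, sep = ":"))
    }
  }
  list(residuals = resid, groups = do.call(rbind, c(groups, make.row.names = FALSE)))
}
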