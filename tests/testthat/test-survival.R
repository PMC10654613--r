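# KM, log-rank, Cox, cutpoint screening, meta-PCNA, residuals.

test_that("KM estimator follows the product-limit construction", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(5, 8, 2), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # all events at 1, 2, 3: S = 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2/3, 1/3, 0))

  # censoring before the first event reduces at-risk but not survival
  km2 <- km_estimate(c(0.5, 1, 2, 3), c(0, 1, 1, 1))
  expect_equal(km2$survival[km2$time == 1], 2/3)
  expect_equal(km2$n_at_risk[km2$time == 1], 3)

  # with no censoring the estimator equals 1 - ECDF
  set.seed(1)
  tm <- rexp(40, 0.1)
  km3 <- km_estimate(tm, rep(1, 40))
  expect_equal(km3$survival, 1 - ecdf(tm)(km3$time), tolerance = 1e-12)

  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "epistrat_contract_error")
  expect_error(km_estimate(c(0, 1), c(1, 1)),
               class = "epistrat_contract_error")
})

test_that("log-rank matches risk-table enumeration and degenerates safely", {
  # duplicated groups: no difference
  tm <- c(1, 2, 3, 1, 2, 3); ev <- rep(1, 6)
  res <- logrank_test(rep(1:2, each = 3), tm, ev)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # A events {1,2}, B events {3,4}: frozen hand risk-table value
  res2 <- logrank_test(c("A", "A", "B", "B"), c(1, 2, 3, 4), rep(1, 4))
  expect_equal(res2$chi2, 2.882353, tolerance = 1e-6)
  expect_equal(res2$df, 1)

  # three groups give df = 2
  res3 <- logrank_test(rep(1:3, each = 3), rep(c(1, 2, 3), 3),
                       rep(1, 9))
  expect_equal(res3$df, 2)

  # invariance to group relabeling and time shifts
  set.seed(2)
  s <- toy_surv(40, hr = 2)
  a <- logrank_test(s$group, s$time, s$event)
  b <- logrank_test(3 - s$group, s$time + 100, s$event)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)

  expect_warning(z <- logrank_test(rep(1:2, 3), 1:6, rep(0, 6)), "no events")
  expect_equal(z$p, 1)
  expect_true(z$flagged)
  expect_error(logrank_test(rep(1, 4), 1:4, rep(1, 4)),
               class = "epistrat_contract_error")
})

test_that("Cox fit estimates, flags separation, and agrees with log-rank", {
  # null covariate: small coefficient most of the time
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 500
    x <- rnorm(n)
    tm <- rexp(n, 0.01)
    fit <- cox_fit(data.frame(x = x), tm, rep(1, n))
    abs(fit$coefficients$coef[1]) < 0.15
  }, logical(1))
  expect_gte(sum(hits), 9)

  # binary covariate perfectly ordering events: monotone likelihood flagged
  n <- 20
  fit_sep <- cox_fit(data.frame(g = rep(0:1, each = 10)),
                     c(1:10, 101:110), rep(1, n))
  expect_false(fit_sep$converged)

  expect_error(cox_fit(data.frame(c = rep(1, 10)), 1:10, rep(1, 10)),
               class = "epistrat_contract_error")

  # score test at beta = 0 equals the log-rank statistic (no ties)
  set.seed(3)
  tm <- sort(rexp(30, 0.01)) * (1 + 1e-9 * (1:30))   # strictly distinct
  ev <- rbinom(30, 1, 0.8)
  grp <- rep(0:1, 15)
  sc <- survival::coxph(survival::Surv(tm, ev) ~ grp)
  lr <- logrank_test(grp, tm, ev)
  expect_equal(unname(summary(sc)$sctest["test"]), lr$chi2,
               tolerance = 1e-6)
})

test_that("cluster comparison spans endpoints and flags collinearity", {
  coh <- generate_cohort(small_config(seed = 4))
  labels <- coh$truth$sample_program
  names(labels) <- coh$clinical$sample_id
  res <- compare_clusters(labels, coh$clinical)
  expect_setequal(names(res), c("pfi", "dss", "os"))
  expect_true(all(vapply(res, function(x) x$logrank$p >= 0 &
                           x$logrank$p <= 1, logical(1))))

  clin2 <- coh$clinical
  clin2$cluster_copy <- as.integer(labels == 2)
  expect_warning(
    res2 <- compare_clusters(labels, clin2,
                             adjust_for = c("age", "cluster_copy"),
                             endpoints = "pfi"),
    "collinear")
  expect_true("cluster_copy" %in% res2$pfi$dropped_covariates)
})

test_that("optimal cutpoint recovers planted splits within minprop bounds", {
  set.seed(5)
  n <- 100
  prog <- rep(0:1, each = 50)
  expr <- prog + rnorm(n, sd = 0.01)
  h <- 0.002 * ifelse(prog == 1, 20, 1)
  tm <- pmax(rexp(n, h), 1e-3)
  cp <- optimal_cutpoint(expr, tm, rep(1, n))
  # the argmax of a maximally selected statistic can sit one sample off the
  # planted boundary; recovery holds up to that granularity
  expect_gte(mean((expr > cp$cutpoint) == (prog == 1)), 0.98)

  # minprop = 0.1, n = 100: the 10 extreme samples per side are excluded
  expr2 <- 1:100
  h2 <- 0.002 * ifelse(expr2 > 95, 10, 1)   # best split is inadmissible
  set.seed(6)
  tm2 <- pmax(rexp(n, h2), 1e-3)
  cp2 <- optimal_cutpoint(expr2, tm2, rep(1, n))
  expect_gte(sum(expr2 > cp2$cutpoint), 10)
  expect_gte(sum(expr2 <= cp2$cutpoint), 10)

  expect_error(optimal_cutpoint(rep(1, 20), 1:20, rep(1, 20)),
               class = "epistrat_contract_error")
  expect_error(optimal_cutpoint(1:20, 1:20, rep(1, 20), minprop = 0.6),
               class = "epistrat_contract_error")

  # the scanned statistic matches survdiff at the chosen split
  sdf <- survival::survdiff(survival::Surv(tm2, rep(1, n)) ~
                              I(expr2 > cp2$cutpoint))
  expect_equal(cp2$statistic^2, unname(sdf$chisq), tolerance = 1e-9)
})

test_that("meta-PCNA signature is the top correlated fraction", {
  coh <- generate_cohort(small_config(seed = 7))
  norm <- normalize_log2(coh$counts)
  # boundary: ceiling to a single gene
  mp1 <- meta_pcna(norm, top_frac = 1e-9)
  expect_length(mp1$signature, 1)
  expect_equal(mp1$signature, names(which.max(mp1$correlations)))
  # score is the per-sample median of signature values
  mp <- meta_pcna(norm, top_frac = 0.05)
  expect_equal(unname(mp$score[3]),
               median(norm$values[mp$signature, 3]))
  expect_error(meta_pcna(norm, anchor_gene = "NOPE"),
               class = "epistrat_contract_error")
})

test_that("prognostic screen reports non-variable genes and is roughly
           calibrated under the global null", {
  # non-variable gene comes back unflagged with a reason code
  coh <- generate_cohort(small_config(seed = 8))
  norm <- normalize_log2(coh$counts)
  genes <- rownames(coh$counts)[1:20]
  scr <- prognostic_screen(norm, coh$clinical, genes = genes,
                           variable_genes = genes[-1])
  expect_equal(scr$reason[scr$gene == genes[1]], "non-variable")
  expect_false(scr$prognostic[scr$gene == genes[1]])
  expect_true(all(scr$p_adj >= scr$p, na.rm = TRUE))

  # pure-noise screen: flagged fraction stays small (the optimal-cutpoint
  # dichotomization is optimistic by design; see the methods vignette)
  fr <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 200; G <- 300
    X <- matrix(rnorm(n * G), G, n,
                dimnames = list(sprintf("N%03d", 1:G), sprintf("S%03d", 1:n)))
    tme <- rexp(n, 1 / 1500); cns <- runif(n, 0, 3000)
    clin <- data.frame(sample_id = colnames(X),
                       time_pfi = pmax(pmin(tme, cns), 1e-3),
                       event_pfi = as.integer(tme <= cns),
                       age = rnorm(n, 60, 10),
                       sex = sample(c("F", "M"), n, TRUE))
    mean(prognostic_screen(X, clin)$prognostic)
  }, numeric(1))
  expect_lte(mean(fr), 0.10)
})

test_that("prognostic residuals count directions and apply the sign test", {
  mk <- function(genes, dirs, progn = TRUE) {
    data.frame(gene = genes, direction = dirs,
               prognostic = rep(progn, length(genes)),
               stringsAsFactors = FALSE)
  }
  # gene A poor-with-high in 3 cohorts, poor-with-low in 1 -> residual +2
  tabs <- list(mk("A", "poor-with-high"), mk("A", "poor-with-high"),
               mk("A", "poor-with-high"), mk("A", "poor-with-low"))
  ann <- data.frame(gene = "A", category = "histone modification")
  res <- prognostic_residuals(tabs, ann, groupings = "all")
  expect_equal(res$residuals$residual[res$residuals$gene == "A"], 2)

  # 8 positives vs 2 negatives: exact two-sided sign-test p = 0.109375
  genes <- paste0("g", 1:10)
  dirs1 <- c(rep("poor-with-high", 8), rep("poor-with-low", 2))
  dirs2 <- c(rep("poor-with-high", 8), rep("poor-with-low", 2))
  tabs2 <- list(mk(genes, dirs1), mk(genes, dirs2))
  ann2 <- data.frame(gene = genes, category = "other")
  res2 <- prognostic_residuals(tabs2, ann2, groupings = "all")
  expect_equal(res2$groups$n_positive, 8)
  expect_equal(res2$groups$n_negative, 2)
  expect_equal(res2$groups$p, 0.109375, tolerance = 1e-12)

  # a gene prognostic nowhere is excluded from the sign counts
  tabs3 <- list(mk(c("A", "B"), rep("poor-with-high", 2), c(TRUE, FALSE)),
                mk(c("A", "B"), rep("poor-with-high", 2), c(TRUE, FALSE)))
  res3 <- prognostic_residuals(tabs3, ann, groupings = "all")
  expect_equal(res3$residuals$residual[res3$residuals$gene == "B"], 0)
  expect_equal(res3$groups$n_positive + res3$groups$n_negative, 1)

  expect_error(prognostic_residuals(tabs3, ann, groupings = "nonsense"),
               class = "epistrat_contract_error")
  expect_error(prognostic_residuals(tabs3[1], ann),
               class = "epistrat_contract_error")
})
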