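# NMF factorization, consensus clustering, validation metrics and signature
# extraction.

test_that("nmf_factorize validates input and recovers exact low-rank data", {
  expect_error(nmf_factorize(matrix(c(-1, 2, 3, 4), 2), 1),
               class = "epistrat_contract_error")
  expect_error(nmf_factorize(matrix(1:6, 2, 3), 2),
               class = "epistrat_contract_error")

  set.seed(10)
  W0 <- matrix(runif(30 * 2), 30, 2)
  H0 <- matrix(runif(2 * 20), 2, 20)
  V <- W0 %*% H0
  dimnames(V) <- list(paste0("g", 1:30), paste0("s", 1:20))
  fit <- nmf_factorize(V, 2, seed = 3, max_iter = 5000, tol = 1e-12)
  d_fit <- kl_oracle(V, fit$W %*% fit$H)
  d_const <- kl_oracle(V, matrix(mean(V), 30, 20))
  expect_lt(d_fit, 1e-6 * d_const)
})

test_that("the KL objective trace is non-increasing on random inputs", {
  for (s in 1:5) {
    set.seed(s)
    V <- matrix(rexp(25 * 12), 25, 12)
    fit <- nmf_factorize(V, 3, seed = s, max_iter = 200)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  }
  # determinism of the seeded initialization
  V <- matrix(rexp(25 * 12), 25, 12)
  expect_identical(nmf_factorize(V, 2, seed = 9)$W,
                   nmf_factorize(V, 2, seed = 9)$W)
})

test_that("consensus clustering separates block-structured data exactly", {
  # two disjoint, strongly expressed gene blocks
  V <- matrix(0.01, 40, 24)
  V[1:20, 1:12] <- 5
  V[21:40, 13:24] <- 5
  dimnames(V) <- list(paste0("g", 1:40), paste0("s", 1:24))
  cc <- consensus_cluster(V, 2, n_runs = 10, seed = 1)
  expect_true(all(cc$consensus %in% c(0, 1)))
  expect_length(unique(cc$labels[1:12]), 1)
  expect_length(unique(cc$labels[13:24]), 1)
  expect_false(cc$labels[1] == cc$labels[24])
  # structural invariants
  expect_equal(cc$consensus, t(cc$consensus))
  expect_true(all(diag(cc$consensus) == 1))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))

  # duplicated samples always co-cluster
  V2 <- cbind(V, dup1 = V[, 1], dup2 = V[, 1])
  cc2 <- consensus_cluster(V2, 2, n_runs = 6, seed = 2)
  expect_equal(unname(cc2$consensus["dup1", "dup2"]), 1)
  expect_equal(unname(cc2$consensus["dup1", "s1"]), 1)

  expect_error(consensus_cluster(V, 2, n_runs = 1),
               class = "epistrat_config_error")
})

test_that("cophenetic coefficient matches direct merge-height enumeration", {
  # perfect two-block 0/1 consensus is already ultrametric
  perfect <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                   c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(as.numeric(cophenetic_coefficient(perfect)), 1)

  # constant off-diagonal: degenerate, flagged
  flat <- matrix(0.5, 4, 4); diag(flat) <- 1
  expect_warning(res <- cophenetic_coefficient(flat), "degenerate|constant")
  expect_true(is.na(res))
  expect_true(attr(res, "degenerate"))

  # 4-sample consensus with one noisy pair: frozen oracle value from
  # hand-built average-linkage merges (heights 0.1, 0.2, then mean 0.8625)
  cons <- matrix(c(1, .9, .1, .2,
                   .9, 1, .15, .1,
                   .1, .15, 1, .8,
                   .2, .1, .8, 1), 4, 4)
  expect_equal(as.numeric(cophenetic_coefficient(cons)), 0.9949966,
               tolerance = 1e-6)

  expect_error(cophenetic_coefficient(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               class = "epistrat_contract_error")
})

test_that("silhouette matches brute-force pairwise evaluation", {
  # points 0,1,2,3 with labels 1,1,2,2: hand value
  pts <- matrix(c(0, 1, 2, 3), ncol = 1)
  expect_equal(silhouette_score(pts, c(1, 1, 2, 2)), 0.4666667,
               tolerance = 1e-6)

  # two tight, far-apart blobs
  set.seed(4)
  blobs <- rbind(matrix(rnorm(40, 0, 0.05), ncol = 2),
                 matrix(rnorm(40, 10, 0.05), ncol = 2))
  expect_gt(silhouette_score(blobs, rep(1:2, each = 20)), 0.95)

  # random labels on i.i.d. data sit near zero
  set.seed(5)
  iid <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(silhouette_score(iid, sample(1:2, 200, TRUE))), 0.1)

  expect_error(silhouette_score(pts, rep(1, 4)),
               class = "epistrat_contract_error")
})

test_that("connectivity matches brute-force neighbor enumeration", {
  # 1-D toy: both points of the small pair see a cross-cluster neighbor
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(connectivity(pts, c(1, 2, 2, 2), L = 1), 2.0)
  # fully separated clusters
  expect_equal(connectivity(pts, c(1, 1, 2, 2), L = 1), 0)
  # single label
  expect_equal(connectivity(pts, rep(1, 4), L = 2), 0)
  expect_error(connectivity(pts, c(1, 1, 2, 2), L = 4),
               class = "epistrat_contract_error")
})

test_that("rank selection takes the metric majority with smallest-k ties", {
  mt <- data.frame(k = 2:4, cophenetic = c(0.99, 0.90, 0.85),
                   silhouette = c(0.5, 0.3, 0.2),
                   connectivity = c(2, 5, 9))
  expect_equal(select_rank(mt), 2)

  mt2 <- data.frame(k = 2:4, cophenetic = c(0.90, 0.99, 0.85),
                    silhouette = c(0.5, 0.3, 0.2),
                    connectivity = c(2, 5, 9))
  expect_equal(select_rank(mt2), 2)    # majority beats cophenetic

  mt3 <- data.frame(k = 2:4, cophenetic = c(0.85, 0.99, 0.90),
                    silhouette = c(0.2, 0.3, 0.5),
                    connectivity = c(2, 5, 9))
  expect_equal(select_rank(mt3), 2)    # three-way split -> smallest k

  expect_error(select_rank(mt[, -2]), class = "epistrat_contract_error")
  expect_error(select_rank(mt[1, ]), class = "epistrat_contract_error")
})

test_that("Kim-Park scores hit their closed-form extremes and select the
           planted specific genes", {
  W <- rbind(spec = c(1, 0), unif = c(0.5, 0.5), mid = c(0.8, 0.2))
  sc <- kim_park_score(W)
  expect_equal(unname(sc["spec"]), 1)
  expect_equal(unname(sc["unif"]), 0)
  expect_true(all(sc >= 0 & sc <= 1))

  # 2 perfectly specific high-magnitude genes among 98 uniform low ones
  W2 <- matrix(0.05, 100, 2)
  W2[1, ] <- c(3, 0)
  W2[2, ] <- c(0, 3)
  rownames(W2) <- paste0("g", 1:100)
  sig <- extract_top_genes(W2)
  expect_setequal(unlist(sig$signatures), c("g1", "g2"))
  expect_equal(sig$signatures$cluster1, "g1")
  expect_equal(sig$signatures$cluster2, "g2")

  expect_error(extract_top_genes(W2[, 1, drop = FALSE]),
               class = "epistrat_contract_error")
})

test_that("outcome labeling identifies the higher-hazard cluster as poor", {
  set.seed(8)
  n <- 200
  cl_lab <- setNames(rep(1:2, each = 100), sprintf("s%03d", 1:n))
  h <- 0.002 * ifelse(cl_lab == 2, 2, 1)    # cluster 2 has HR 2
  tm <- rexp(n, h)
  clin <- data.frame(sample_id = names(cl_lab),
                     time_pfi = pmax(tm, 1e-3),
                     event_pfi = 1L)
  out <- label_clusters_by_outcome(cl_lab, clin)
  expect_equal(unname(out["2"]), "poor")
  expect_equal(unname(out["1"]), "better")

  # identical survival distributions: unlabeled, flagged
  clin2 <- clin
  clin2$time_pfi <- rep(clin$time_pfi[1:100], 2)
  expect_warning(out2 <- label_clusters_by_outcome(cl_lab, clin2),
                 "unlabeled")
  expect_null(out2)

  # all censored: unlabeled, flagged
  clin3 <- clin; clin3$event_pfi <- 0L
  expect_warning(out3 <- label_clusters_by_outcome(cl_lab, clin3),
                 "unlabeled|no events")
  expect_null(out3)
})
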