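# Shared fixture builders. Everything is generated in code; no stored data.

# A small, fast cohort configuration for structural tests (the default-sized
# configuration is reserved for the recovery/acceptance experiments).
small_config <- function(seed = 1, ...) {
  cohort_config(n_samples = 60, n_genes = 400, n_epifactors = 120,
                signature_size = 15, prolif_module_size = 20, seed = seed, ...)
}

# Exponential survival toy with optional group hazard ratio.
toy_surv <- function(n, hr = 1, censor = 0.3, seed = 1) {
  set.seed(seed)
  group <- rep(1:2, length.out = n)
  h <- 0.001 * ifelse(group == 2, hr, 1)
  t_ev <- rexp(n, h)
  t_c <- if (censor > 0) runif(n, 0, quantile(t_ev, 1 - censor) * 2) else Inf
  list(time = pmax(pmin(t_ev, t_c), 1e-3), event = as.integer(t_ev <= t_c),
       group = group)
}

# Generalized KL divergence, written independently of the package internals.
kl_oracle <- function(V, WH) {
  sum(ifelse(V > 0, V * log(V / WH) - V + WH, WH))
}

# Two-tailed Fisher p by exhaustive hypergeometric enumeration.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Single-sample running-sum enrichment score, naive loop implementation.
ss_score_oracle <- function(x, in_set, tau = 0.25) {
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  w <- r^tau
  sumw <- sum(w[in_set])
  n_out <- sum(!in_set)
  run <- 0; total <- 0
  for (i in ord) {
    run <- run + if (in_set[i]) w[i] / sumw else -1 / n_out
    total <- total + run
  }
  total
}

# Adjusted Rand index (two labelings), direct pair-counting implementation.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expd <- si * sj / choose(sum(tab), 2)
  mx <- (si + sj) / 2
  if (mx == expd) return(1)
  (sij - expd) / (mx - expd)
}
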