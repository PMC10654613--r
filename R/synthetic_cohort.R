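# Synthetic tumor cohorts with planted expression programs, a proliferation
# module, survival outcomes and annotations, plus ground-truth labels, so the
# downstream stratification can be verified end to end.

# Evaluate a block with a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated tumor cohort: two (or
#' more) latent expression programs over epifactor genes, negative-binomial
#' counts, a PCNA-anchored proliferation co-expression module, and
#' exponential survival whose hazard depends on program membership.
#'
#' @param n_samples number of tumors.
#' @param n_genes total genes (signature + proliferation + background).
#' @param n_epifactors genes carrying the epifactor annotation (<= n_genes).
#' @param n_programs number of planted expression programs.
#' @param signature_size signature genes per program (drawn from epifactors).
#' @param effect_log2fc mean log2 fold-change of a signature gene in tumors
#'   of its own program.
#' @param nb_dispersion negative-binomial dispersion phi in
#'   var = mu + phi * mu^2.
#' @param libsize_range multiplicative library-size interval (log-uniform).
#' @param prolif_module_size size of the proliferation module; contains the
#'   literal gene "PCNA".
#' @param prolif_cor target Pearson correlation of module genes with PCNA on
#'   the log scale.
#' @param baseline_hazard events per day for program-1 tumors.
#' @param cluster_log_hr log hazard ratio of program 2 vs program 1
#'   (programs beyond 2 scale linearly).
#' @param censor_frac target fraction of censored survival times
#'   (uniform administrative censoring).
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 200, n_genes = 3000, n_epifactors = 720,
                          n_programs = 2, signature_size = 40,
                          effect_log2fc = 2.0, nb_dispersion = 0.2,
                          libsize_range = c(0.5, 2.0),
                          prolif_module_size = 30, prolif_cor = 0.8,
                          baseline_hazard = 1 / 1500, cluster_log_hr = 0.7,
                          censor_frac = 0.4, seed = 1) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_epifactors = n_epifactors, n_programs = n_programs,
              signature_size = signature_size, effect_log2fc = effect_log2fc,
              nb_dispersion = nb_dispersion, libsize_range = libsize_range,
              prolif_module_size = prolif_module_size, prolif_cor = prolif_cor,
              baseline_hazard = baseline_hazard, cluster_log_hr = cluster_log_hr,
              censor_frac = censor_frac, seed = seed)
  for (f in c("n_samples", "n_genes", "n_epifactors", "n_programs",
              "signature_size", "prolif_module_size"))
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1 || cfg[[f]] %% 1 != 0)
      config_error(paste(f, "must be a positive integer"))
  if (n_epifactors > n_genes) config_error("n_epifactors exceeds n_genes")
  if (signature_size * n_programs > n_epifactors)
    config_error("signature genes do not fit among the epifactors")
  if (prolif_module_size > n_genes - n_epifactors)
    config_error("proliferation module does not fit among non-epifactor genes")
  if (censor_frac < 0 || censor_frac >= 1)
    config_error("censor_frac must lie in [0, 1)")
  if (prolif_cor <= 0 || prolif_cor >= 1)
    config_error("prolif_cor must lie in (0, 1)")
  if (nb_dispersion < 0 || baseline_hazard <= 0)
    config_error("nb_dispersion must be >= 0 and baseline_hazard > 0")
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      diff(libsize_range) < 0)
    config_error("libsize_range must be an increasing positive interval")
  class(cfg) <- "cohort_config"
  cfg
}

# The 19 multiprotein-complex names used by the annotation.
epifactor_complexes <- c(
  "SWI/SNF", "NuRD", "PRC1", "PRC2", "COMPASS", "SAGA", "NuA4", "SIN3",
  "CoREST", "ISWI", "INO80", "SRCAP", "MOZ/MORF", "HBO1", "NSL", "SET1B",
  "ORC", "MCM", "FACT")

# Gene-level structure derived deterministically from the config seed, shared
# by the bulk and single-cell generators so signatures transfer between them.
gene_setup <- function(config) {
  with_seed(derive_seed(config$seed, "simulate"), {
    G <- config$n_genes; E <- config$n_epifactors
    ids <- sprintf("G%06d", seq_len(G))
    epi_idx <- seq_len(E)
    # proliferation module lives among non-epifactor genes; anchor is PCNA
    prolif_idx <- E + seq_len(config$prolif_module_size)
    ids[prolif_idx[1]] <- "PCNA"

    sig_idx <- matrix(sample(epi_idx, config$signature_size * config$n_programs),
                      ncol = config$n_programs)
    role <- rep("background", G)
    for (q in seq_len(config$n_programs))
      role[sig_idx[, q]] <- paste0("signature_p", q)
    role[prolif_idx] <- "proliferation"

    # heterogeneous baselines give the wide spread of per-gene variability
    # that the SD-based variable-gene selection expects
    log2_base <- rnorm(G, mean = 5, sd = 2)
    log2_base[prolif_idx] <- rnorm(length(prolif_idx), mean = 7, sd = 1)
    lfc <- pmax(0.25, rnorm(G, config$effect_log2fc, 0.3))

    # latent-factor loading calibrated per gene so cor(gene, PCNA) on the
    # log scale is approximately prolif_cor under NB noise
    mu0 <- 2^log2_base
    sd_noise <- sqrt(1 / mu0 + config$nb_dispersion) / log(2)
    alpha <- rep(0, G)
    alpha[prolif_idx] <- sd_noise[prolif_idx] *
      sqrt(config$prolif_cor / (1 - config$prolif_cor))

    category <- sample(c("DNA modification", "histone modification",
                         "chromatin remodeling", "other"),
                       E, replace = TRUE, prob = c(0.15, 0.45, 0.25, 0.15))
    subrole <- ifelse(category %in% c("DNA modification", "histone modification"),
                      sample(c("writer", "eraser", "reader"), E, replace = TRUE),
                      NA_character_)
    mark <- ifelse(!is.na(subrole) & subrole %in% c("writer", "eraser"),
                   sample(c("acetylation", "methylation", "phosphorylation",
                            "ubiquitination"), E, replace = TRUE),
                   NA_character_)
    n_cplx <- sample(0:2, E, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    complexes <- vapply(n_cplx, function(k)
      paste(sort(sample(epifactor_complexes, k)), collapse = ";"), character(1))

    annotation <- data.frame(
      gene = ids[epi_idx], is_epifactor = TRUE, category = category,
      subrole = subrole, mark = mark, complexes = complexes,
      stringsAsFactors = FALSE)

    list(ids = ids, epi_idx = epi_idx, sig_idx = sig_idx,
         prolif_idx = prolif_idx, role = role, log2_base = log2_base,
         lfc = lfc, alpha = alpha, annotation = annotation)
  })
}

# Sample-level structure (program membership, library sizes, demographics),
# deterministic from the seed and shared with the alteration generator.
# `replicate` redraws the samples while keeping the gene-level structure
# (signatures, baselines) fixed, for held-out cohorts of the same population.
sample_setup <- function(config, replicate = 1L) {
  with_seed(derive_seed(config$seed, "simulate") + 7919L * replicate + 1L, {
    n <- config$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    program <- sample(rep_len(seq_len(config$n_programs), n))
    libsize <- exp(runif(n, log(config$libsize_range[1]),
                         log(config$libsize_range[2])))
    age <- pmin(90, pmax(30, rnorm(n, 60, 10)))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    purity_cpe <- rbeta(n, 8, 2)
    purity_chat <- rbeta(n, 7, 2)
    list(ids = ids, program = program, libsize = libsize, age = age,
         sex = sex, purity_cpe = purity_cpe, purity_chat = purity_chat)
  })
}

# Administrative-censoring horizon achieving the target censoring fraction
# for per-sample exponential hazards. P(censored | h, tau) = 1 - evfrac.
censor_horizon <- function(hazards, censor_frac) {
  if (censor_frac <= 0) return(Inf)
  event_frac <- function(tau)
    mean(1 - (1 - exp(-hazards * tau)) / (hazards * tau))
  uniroot(function(tau) event_frac(tau) - (1 - censor_frac),
          lower = 1e-6, upper = 1e9, tol = 1e-8)$root
}

draw_endpoint <- function(hazards, censor_frac) {
  n <- length(hazards)
  t_event <- rexp(n, rate = hazards)
  tau <- censor_horizon(hazards, censor_frac)
  t_cens <- if (is.finite(tau)) runif(n, 0, tau) else rep(Inf, n)
  list(time = pmax(pmin(t_event, t_cens), 1e-3),
       event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic bulk tumor cohort
#'
#' Draws negative-binomial counts with mean
#' `mu_gs = libsize_s * baseline_g * 2^(lfc_g)` for signature genes in
#' tumors of their own program, a shared latent proliferation factor added on
#' the log scale for the PCNA module, censored exponential survival times for
#' three endpoints (PFI, DSS, OS) whose hazard depends on program membership
#' and weakly on age, and two Beta-distributed purity metrics.
#'
#' @param config a [cohort_config()].
#' @param replicate positive integer; redraws samples, outcomes and counts
#'   while keeping the gene-level population structure (signature identities,
#'   baselines, annotation) fixed. Use `replicate = 2` for a held-out
#'   validation cohort with the same programs.
#' @return list with elements `counts` (genes x samples integer matrix),
#'   `clinical` (data.frame with survival endpoints, age, sex, purity),
#'   `annotation` (epifactor annotation data.frame), and `truth`
#'   (`sample_program`, `gene_role` named vectors).
#' @export
generate_cohort <- function(config, replicate = 1L) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  gs <- gene_setup(config)
  ss <- sample_setup(config, replicate)
  with_seed(derive_seed(config$seed, "simulate") + 7919L * replicate + 2L, {
    G <- config$n_genes; n <- config$n_samples
    log2_mu <- matrix(gs$log2_base, G, n)
    for (q in seq_len(config$n_programs)) {
      in_q <- which(ss$program == q)
      log2_mu[gs$sig_idx[, q], in_q] <-
        log2_mu[gs$sig_idx[, q], in_q] + gs$lfc[gs$sig_idx[, q]]
    }
    z <- rnorm(n)                       # proliferation latent factor
    log2_mu <- log2_mu + outer(gs$alpha, z)
    mu <- sweep(2^log2_mu, 2, ss$libsize, `*`)
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) rnbinom(G * n, mu = mu, size = size)
      else rpois(G * n, lambda = mu),
      G, n, dimnames = list(gs$ids, ss$ids))

    hr <- exp(config$cluster_log_hr * (ss$program - 1) + 0.02 * (ss$age - 60))
    endpoints <- lapply(c(pfi = 1, dss = 0.8, os = 0.6), function(scale)
      draw_endpoint(config$baseline_hazard * scale * hr, config$censor_frac))

    clinical <- data.frame(
      sample_id = ss$ids,
      time_pfi = endpoints$pfi$time, event_pfi = endpoints$pfi$event,
      time_dss = endpoints$dss$time, event_dss = endpoints$dss$event,
      time_os = endpoints$os$time, event_os = endpoints$os$event,
      age = ss$age, sex = ss$sex,
      purity_cpe = ss$purity_cpe, purity_chat = ss$purity_chat,
      stringsAsFactors = FALSE)

    truth <- list(sample_program = setNames(ss$program, ss$ids),
                  gene_role = setNames(gs$role, gs$ids))
    structure(list(counts = counts, clinical = clinical,
                   annotation = gs$annotation, truth = truth, config = config),
              class = "epistrat_cohort")
  })
}

#' Generate a synthetic single-cell expression matrix
#'
#' Cells belong to one of four groups: expressing neither planted program
#' ("none"), program A, program B, or both. Cells in a group over-express the
#' corresponding bulk signature genes (same gene identities as
#' [generate_cohort()] under the same config). Counts are Poisson draws over
#' a cell-specific sequencing depth; the returned matrix holds log-normalized
#' expression `ln(1 + 1e4 * count / depth)`.
#'
#' @param config a [cohort_config()]; defines genes, signatures, and seed.
#' @param n_cells number of cells (>= 4).
#' @param group_fracs fractions for groups (none, A, B, both); must sum to 1.
#' @return list with `cells` (genes x cells matrix) and `truth$cell_group`.
#' @export
generate_single_cell <- function(config, n_cells = 400,
                                 group_fracs = c(0.25, 0.25, 0.25, 0.25)) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  if (n_cells < 4) config_error("n_cells must be at least 4")
  if (length(group_fracs) != 4 || any(group_fracs < 0) ||
      abs(sum(group_fracs) - 1) > 1e-9)
    config_error("group_fracs must be 4 nonnegative fractions summing to 1")
  if (config$n_programs < 2)
    config_error("single-cell generation needs at least 2 programs")
  gs <- gene_setup(config)
  with_seed(derive_seed(config$seed, "sc_score") + 1L, {
    counts_per_group <- diff(round(cumsum(c(0, group_fracs)) * n_cells))
    group <- sample(rep(c("none", "A", "B", "both"), counts_per_group))
    barcodes <- sprintf("C%05d", seq_len(n_cells))

    base_rel <- 2^gs$log2_base
    sigA <- gs$sig_idx[, 1]; sigB <- gs$sig_idx[, 2]
    depth <- round(runif(n_cells, 2000, 10000))
    counts <- vapply(seq_len(n_cells), function(ci) {
      rel <- base_rel
      if (group[ci] %in% c("A", "both")) rel[sigA] <- rel[sigA] * 2^gs$lfc[sigA]
      if (group[ci] %in% c("B", "both")) rel[sigB] <- rel[sigB] * 2^gs$lfc[sigB]
      rpois(config$n_genes, depth[ci] * rel / sum(rel))
    }, numeric(config$n_genes))
    dimnames(counts) <- list(gs$ids, barcodes)
    totals <- colSums(counts)
    cells <- log1p(sweep(counts, 2, 1e4 / totals, `*`))
    list(cells = cells,
         truth = list(cell_group = setNames(group, barcodes)),
         config = config)
  })
}

#' Generate a binary alteration matrix over the cohort's samples
#'
#' Each listed gene is altered (mutation or copy-number event) independently
#' in the samples of planted program 1 with probability `f1` and of program 2
#' with probability `f2`.
#'
#' @param config a [cohort_config()] (defines samples and their programs).
#' @param freqs_by_cluster data.frame or matrix with rownames = gene ids and
#'   two columns of per-cluster alteration frequencies in [0, 1].
#' @param kind "mutation" or "CNA"; stored as an attribute.
#' @return binary genes x samples matrix with attribute `kind`.
#' @export
generate_alterations <- function(config, freqs_by_cluster, kind = "mutation") {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  freqs <- as.matrix(freqs_by_cluster)
  if (ncol(freqs) != 2 || any(freqs < 0) || any(freqs > 1))
    config_error("freqs_by_cluster needs two per-cluster columns in [0, 1]")
  gs <- gene_setup(config)
  unknown <- setdiff(rownames(freqs), gs$ids)
  if (length(unknown))
    contract_error(paste("unknown genes:", paste(head(unknown, 5), collapse = ", ")))
  ss <- sample_setup(config)
  cluster12 <- pmin(ss$program, 2L)
  with_seed(derive_seed(config$seed, "enrich") + 1L, {
    probs <- freqs[, cluster12, drop = FALSE]   # genes x samples
    alt <- matrix(rbinom(length(probs), 1, probs), nrow(freqs),
                  config$n_samples,
                  dimnames = list(rownames(freqs), ss$ids))
    attr(alt, "kind") <- kind
    alt
  })
}
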