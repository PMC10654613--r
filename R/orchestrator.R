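# End-to-end pipeline: simulate -> preprocess -> stratify -> survive ->
# screen -> enrich -> validate -> sc_score, with a machine-readable manifest.

pipeline_stages <- c("simulate", "preprocess", "stratify", "survive",
                     "screen", "enrich", "validate", "sc_score")

stage_deps <- list(
  simulate = character(0),
  preprocess = "simulate",
  stratify = "preprocess",
  survive = "stratify",
  screen = "preprocess",
  enrich = "stratify",
  validate = "survive",
  sc_score = "survive")

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Accepts a
#' YAML or JSON file path, a list, or nothing (defaults). All randomness in
#' the run flows from the single `seed`, from which per-stage seeds are
#' derived deterministically.
#'
#' @param config path to a YAML/JSON file, or a list with any of the fields
#'   `cohort` (arguments of [cohort_config()]), `stages`, `ranks`, `n_runs`,
#'   `purity_threshold`, `n_cells`, `seed`.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) config_error("config must be a list or a file path")
  defaults <- list(cohort = list(), stages = pipeline_stages, ranks = 2:4,
                   n_runs = 30, purity_threshold = 0.70, n_cells = 400,
                   seed = 7)
  cfg <- modifyList(defaults, config)
  bad <- setdiff(cfg$stages, pipeline_stages)
  if (length(bad))
    config_error(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  for (st in cfg$stages) {
    missing_dep <- setdiff(stage_deps[[st]], cfg$stages)
    if (length(missing_dep))
      dependency_error(sprintf(
        "stage '%s' requires stage '%s', which is not requested",
        st, missing_dep[1]))
  }
  cfg$cohort$seed <- cfg$seed
  cfg$cohort <- do.call(cohort_config, cfg$cohort)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full stratification pipeline
#'
#' Executes the requested stages in order on a synthetic cohort, writing
#' every stage output as TSV/JSON under `out_dir` together with a run
#' manifest (config snapshot, per-stage seeds, md5 digests of every output
#' file, package version, timestamps). Identical config and seed reproduce
#' identical output digests.
#'
#' @param config a [pipeline_config()], list, or YAML/JSON path.
#' @param out_dir output directory (created if absent).
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("epistrat_run_")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name, writer = write_tsv) {
    path <- file.path(out_dir, name)
    writer(x, path)
    files <<- c(files, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, path)
    path
  }
  state <- new.env(parent = emptyenv())
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  for (st in intersect(pipeline_stages, cfg$stages)) {
    switch(st,
      simulate = {
        state$cohort <- generate_cohort(cfg$cohort)
        emit(state$cohort$counts, "counts.tsv")
        emit(state$cohort$clinical, "clinical.tsv")
        emit(state$cohort$annotation, "annotation.tsv")
        emit(data.frame(sample_id = names(state$cohort$truth$sample_program),
                        program = unname(state$cohort$truth$sample_program)),
             "truth_sample_program.tsv")
      },
      preprocess = {
        keep <- filter_samples(state$cohort$clinical, cfg$purity_threshold,
                               min_cohort = 70)
        counts <- state$cohort$counts[, keep, drop = FALSE]
        state$norm <- normalize_log2(counts)
        state$varsel <- select_variable_epifactors(state$norm,
                                                   state$cohort$annotation)
        emit(data.frame(sample_id = colnames(counts),
                        size_factor = unname(state$norm$size_factors)),
             "size_factors.tsv")
        emit(data.frame(gene = state$varsel$genes, sd = state$varsel$sds),
             "variable_epifactors.tsv")
        emit_json(list(sd_cutoff = state$varsel$cutoff,
                       n_selected = length(state$varsel$genes),
                       in_range = state$varsel$in_range),
                  "variable_epifactors.json")
      },
      stratify = {
        V <- state$norm$values[state$varsel$genes, , drop = FALSE]
        seed <- derive_seed(cfg$seed, "stratify")
        runs <- lapply(cfg$ranks, function(k)
          consensus_cluster(V, k, n_runs = cfg$n_runs, seed = seed + 1000L * k))
        names(runs) <- paste0("k", cfg$ranks)
        metric_table <- data.frame(
          k = cfg$ranks,
          cophenetic = vapply(runs, function(r) r$metrics$cophenetic, 1),
          silhouette = vapply(runs, function(r) r$metrics$silhouette, 1),
          connectivity = vapply(runs, function(r) r$metrics$connectivity, 1))
        state$chosen_k <- select_rank(metric_table)
        state$consensus <- runs[[paste0("k", state$chosen_k)]]
        state$signatures <- extract_top_genes(state$consensus$fit$W)
        emit_json(metric_table, "cluster_metrics.json")
        emit(state$consensus$consensus, "consensus.tsv")
        emit(state$consensus$fit$W, "W.tsv")
        emit(state$consensus$fit$H, "H.tsv")
        emit(state$signatures$table, "signature_scores.tsv")
        emit(state$signatures$signatures, "signatures.gmt", write_gmt)
      },
      survive = {
        outcome <- label_clusters_by_outcome(state$consensus$labels,
                                             state$cohort$clinical)
        state$outcome <- outcome
        state$signatures$outcome_label <- outcome
        cmp <- compare_clusters(state$consensus$labels, state$cohort$clinical)
        emit(data.frame(sample_id = names(state$consensus$labels),
                        cluster = unname(state$consensus$labels),
                        outcome = if (is.null(outcome)) NA else
                          unname(outcome[as.character(state$consensus$labels)])),
             "cluster_labels.tsv")
        emit_json(lapply(cmp, function(x)
          list(logrank_p = x$logrank$p, cox_cluster_p = x$cluster_p)),
          "cluster_survival.json")
      },
      screen = {
        mp <- meta_pcna(state$norm)
        clin <- state$cohort$clinical
        clin$meta_pcna_score <- mp$score[clin$sample_id]
        base_screen <- prognostic_screen(
          state$norm, clin, genes = state$cohort$annotation$gene,
          variable_genes = state$varsel$genes)
        adj_screen <- prognostic_screen(
          state$norm, clin, genes = state$varsel$genes,
          variable_genes = state$varsel$genes,
          adjust_for = c("age", "sex", "meta_pcna_score"))
        base_screen$proliferation_independent <-
          base_screen$prognostic &
          base_screen$gene %in% adj_screen$gene[adj_screen$prognostic]
        state$screen <- base_screen
        emit(base_screen, "prognostic_table.tsv")
        emit(data.frame(gene = mp$signature), "meta_pcna_signature.tsv")
      },
      enrich = {
        universe <- state$varsel$genes
        top <- setNames(universe %in% unlist(state$signatures$signatures),
                        universe)
        ann <- state$cohort$annotation
        members <- strsplit(ann$complexes, ";", fixed = TRUE)
        complexes <- lapply(setNames(nm = epifactor_complexes), function(cx)
          ann$gene[vapply(members, function(m) cx %in% m, logical(1))])
        state$enrichment <- permutation_enrichment(
          top, complexes, n_perm = 10000,
          seed = derive_seed(cfg$seed, "enrich"))
        emit(state$enrichment, "complex_enrichment.tsv")
      },
      validate = {
        if (is.null(state$outcome) ||
            any(vapply(state$signatures$signatures, length, integer(1)) == 0)) {
          warning("clusters unlabeled or a signature is empty; validation classification skipped",
                  call. = FALSE)
        } else {
          val <- generate_cohort(cfg$cohort, replicate = 2L)
          vnorm <- normalize_log2(val$counts)
          poor_cl <- names(state$outcome)[state$outcome == "poor"]
          better_cl <- names(state$outcome)[state$outcome == "better"]
          calls <- classify_by_signatures(
            vnorm,
            state$signatures$signatures[[paste0("cluster", poor_cl)]],
            state$signatures$signatures[[paste0("cluster", better_cl)]])
          emit(calls, "validation_calls.tsv")
        }
      },
      sc_score = {
        sigs <- state$signatures$signatures
        if (any(vapply(sigs, length, integer(1)) == 0)) {
          warning("a cluster signature is empty; single-cell scoring skipped",
                  call. = FALSE)
          next
        }
        sc <- generate_single_cell(cfg$cohort, n_cells = cfg$n_cells)
        seed <- derive_seed(cfg$seed, "sc_score")
        s1 <- module_score(sc$cells, sigs[[1]], seed = seed)
        s2 <- module_score(sc$cells, sigs[[2]], seed = seed + 1L)
        grp <- assign_four_groups(s1, s2)
        de <- one_vs_rest_de(sc$cells, grp$group,
                             genes = unlist(sigs, use.names = FALSE))
        emit(grp, "cell_groups.tsv")
        emit(de, "cell_de.tsv")
        state$sc_groups <- grp
      })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("epistrat")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    stage_seeds = setNames(lapply(pipeline_stages, function(s)
      derive_seed(cfg$seed, s)), pipeline_stages),
    config = cfg[setdiff(names(cfg), "cohort")],
    cohort_config = unclass(cfg$cohort),
    files = lapply(setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
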