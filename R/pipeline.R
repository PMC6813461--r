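# End-to-end orchestration: one entry point running the stages in order on
# a simulated (or supplied) cohort, with seeded reproducibility, per-stage
# outputs, and a plain-text log.

#' Default pipeline configuration
#'
#' Bundles every stage's parameters: the cohort simulation settings, the
#' arcsinh cofactor, clustering sizes (500 clusters for the main arm, 100
#' for the stimulation arm), the 5 percent density-dependent downsampling
#' target, permutation-test and t-SNE settings, the area definitions, and
#' the master seed from which each stage derives its own seed by a fixed
#' offset scheme (see [run_pipeline()]).
#'
#' @param seed Master seed.
#' @param k_main,k_stim Cluster counts for the main and stimulation arms.
#' @param downsample Target downsampling fraction.
#' @param cells_per_sample Cells per simulated sample.
#' @param tsne_cells Equal per-sample cell count for embeddings.
#' @param stimulated Simulate and analyse the stimulation arm.
#' @param ... Overrides merged into the configuration list.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 42L, k_main = 500, k_stim = 100,
                            downsample = 0.05, cells_per_sample = 10000,
                            tsne_cells = 500, stimulated = FALSE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    cofactor = 5,
    k_main = k_main, k_stim = k_stim,
    downsample = downsample,
    clustering_set = "all33",
    alpha = 5,
    perm_mode = "auto", n_perm = 10000, alpha_level = 0.05,
    tsne = list(n_per_sample = tsne_cells, perplexity = 30,
                iterations = 1000),
    embed_markers = c("CD11b", "CD16"),
    area_rules = default_area_rules("neutrophil"),
    correlate_covariate = "duration_months",
    cohort = cohort_spec(cells_per_sample = cells_per_sample,
                         stimulated = stimulated, seed = seed)
  )
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = c("pipeline_config", "list"))
}

log_line <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

write_stage_output <- function(out_dir, stage, name, df) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(file.path(out_dir, stage), showWarnings = FALSE,
             recursive = TRUE)
  write.csv(df, file.path(out_dir, stage, paste0(name, ".csv")),
            row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order: `simulate` (synthetic
#' cohort with ground truth), `cluster` (SPADE-style tree), `phenotype`
#' (categorical heatmap + annotation), `diffabund` (enrichment trends and
#' permutation tests), `subpop` (population isolation, area assignment,
#' area percentages and MSI), `correlate` (subpopulation abundance vs
#' clinical covariate), `stimulate` (cytokine response scoring, only when
#' the cohort carries stimulated mates), and `report` (summary tables).
#' Each stage checks its prerequisites and derives its seed from the master
#' seed by a fixed offset (stage index), so any stage re-runs reproducibly
#' in isolation. When `out_dir` is given, every stage writes its tables as
#' CSV and appends to `pipeline.log` (ISO-8601 timestamps, configuration
#' hash in every line).
#'
#' @param config A [pipeline_config()].
#' @param stages Ordered subset of the stage names above.
#' @param out_dir Optional output directory.
#' @param cohort Optional pre-built `cytof_cohort` (skips `simulate`).
#' @return A named list of stage results (class `cytoforge_run`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "cluster", "phenotype",
                                    "diffabund", "subpop", "correlate",
                                    "report"),
                         out_dir = NULL, cohort = NULL) {
  all_stages <- c("simulate", "cluster", "phenotype", "diffabund", "subpop",
                  "correlate", "stimulate", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "area_rules")])
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(out_dir, "pipeline.log")
  }
  state <- list(config = config, config_hash = cfg_hash)
  need <- function(what, stage, from) {
    if (is.null(state[[what]])) {
      abort(paste0("stage '", stage, "' needs '", from,
                   "' to run first"), class = "cytoforge_dependency_error")
    }
  }
  for (stage in all_stages[all_stages %in% stages]) {
    t0 <- Sys.time()
    if (stage == "simulate") {
      state$cohort <- cohort %||% simulate_cohort(config$cohort)
      write_stage_output(out_dir, stage, "clinical", state$cohort$clinical)
      write_stage_output(out_dir, stage, "ground_truth", state$cohort$truth)
    } else if (stage == "cluster") {
      state$cohort <- state$cohort %||% cohort
      need("cohort", stage, "simulate")
      unstim <- purrr::keep(state$cohort$samples,
                            ~ .x$.condition[1] == "unstimulated")
      state$tree <- spade_tree(
        unstim,
        markers = clustering_markers(state$cohort$panel,
                                     config$clustering_set),
        k = config$k_main, downsample_fraction = config$downsample,
        alpha = config$alpha, seed = derive_seed(config$seed, 2L))
      write_stage_output(out_dir, stage, "abundance", state$tree$abundance)
      write_stage_output(out_dir, stage, "mst", state$tree$mst)
    } else if (stage == "phenotype") {
      need("tree", stage, "cluster")
      state$ranges <- marker_ranges(state$tree$events)
      state$categories <- categorize_clusters(state$tree, state$ranges)
      state$annotation <- annotate_clusters(state$categories)
      write_stage_output(out_dir, stage, "categories",
                         as.data.frame(state$categories))
      write_stage_output(out_dir, stage, "annotation", state$annotation)
    } else if (stage == "diffabund") {
      need("tree", stage, "cluster")
      need("annotation", stage, "phenotype")
      groups <- setNames(state$cohort$clinical$group,
                         state$cohort$clinical$patient)
      state$diffabund <- test_abundance(
        state$tree$abundance, groups, mode = config$perm_mode,
        n_perm = config$n_perm, alpha = config$alpha_level,
        seed = derive_seed(config$seed, 4L))
      state$enrichment_summary <- summarize_enrichment(state$diffabund,
                                                       state$annotation)
      write_stage_output(out_dir, stage, "differential_abundance",
                         state$diffabund)
      write_stage_output(out_dir, stage, "enrichment_by_cell_type",
                         state$enrichment_summary$by_cell_type)
    } else if (stage == "subpop") {
      need("tree", stage, "cluster")
      need("annotation", stage, "phenotype")
      iso <- isolate_population(state$tree, state$annotation, "neutrophil")
      iso <- assign_areas(iso, config$area_rules)
      state$neutrophils <- iso
      state$embedding <- embed_cells(
        iso, config$embed_markers,
        n_per_sample = config$tsne$n_per_sample,
        perplexity = config$tsne$perplexity,
        iterations = config$tsne$iterations,
        seed = derive_seed(config$seed, 6L))
      write_stage_output(
        out_dir, stage, "embedding",
        state$embedding[, c("tsne1", "tsne2", ".sample_id", ".group")])
      state$area_stats <- area_percentages(
        iso, expected_samples = state$cohort$clinical$patient,
        mode = config$perm_mode, n_perm = config$n_perm,
        seed = derive_seed(config$seed, 5L))
      state$msi <- compare_msi(iso, "CD11b", mode = config$perm_mode,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, 5L))
      write_stage_output(out_dir, stage, "area_per_sample",
                         state$area_stats$per_sample)
      write_stage_output(out_dir, stage, "area_pooled",
                         state$area_stats$pooled)
      write_stage_output(out_dir, stage, "area_tests",
                         state$area_stats$tests)
    } else if (stage == "correlate") {
      need("area_stats", stage, "subpop")
      area2 <- state$area_stats$per_sample
      area2 <- area2[area2$area != "rest", , drop = FALSE]
      pct <- tibble::tibble(patient = area2$sample_id,
                            value = area2$percentage)
      state$correlation <- correlate_abundance(
        pct, state$cohort$clinical, config$correlate_covariate)
      write_stage_output(out_dir, stage, "correlation",
                         tidy(state$correlation))
    } else if (stage == "stimulate") {
      need("cohort", stage, "simulate")
      state$stimulation <- stimulation_response(
        state$cohort, k = config$k_stim,
        downsample_fraction = config$downsample,
        seed = derive_seed(config$seed, 7L))
      state$stim_tests <- compare_response(
        state$stimulation, mode = config$perm_mode, n_perm = config$n_perm,
        seed = derive_seed(config$seed, 7L))
      write_stage_output(out_dir, stage, "percent_positive",
                         state$stimulation$scores)
      write_stage_output(out_dir, stage, "response_tests", state$stim_tests)
    } else if (stage == "report") {
      report <- list()
      if (!is.null(state$enrichment_summary)) {
        report$overall_ra_enriched <-
          state$enrichment_summary$overall_ra_enriched
      }
      if (!is.null(state$area_stats)) {
        report$pooled_areas <- state$area_stats$pooled
      }
      if (!is.null(state$correlation)) {
        report$correlation <- tidy(state$correlation)
      }
      state$report <- report
      if (!is.null(out_dir)) {
        jsonlite::write_json(
          purrr::map(report, ~ if (is.data.frame(.x)) .x else unbox_num(.x)),
          file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
      }
    }
    log_line(log_path, "config=", cfg_hash, " seed=", config$seed,
             " stage=", stage, " elapsed=",
             sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))))
  }
  structure(state, class = "cytoforge_run")
}

unbox_num <- function(x) if (length(x) == 1) jsonlite::unbox(x) else x

#' @export
print.cytoforge_run <- function(x, ...) {
  done <- intersect(c("cohort", "tree", "categories", "annotation",
                      "diffabund", "area_stats", "correlation",
                      "stimulation", "report"), names(x))
  cat("<cytoforge_run> completed: ", paste(done, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
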