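# TLR-stimulation cytokine response: control-referenced positivity gating
# and percent-positive quantification per population and cytokine, with
# stimulated-vs-control and RA-vs-healthy permutation comparisons.

#' Cytokine positivity threshold from control cells
#'
#' The threshold is the 99th percentile (configurable) of the cytokine's
#' transformed intensity in unstimulated (PBS) control cells of the matched
#' population, so control samples score about 1 percent positive by
#' construction.
#'
#' @param control_events Control cells of one population (>= `min_cells`).
#' @param cytokine Marker name.
#' @param percentile Gate percentile in (0, 1).
#' @param min_cells Minimum control cell count.
#' @return The threshold (scalar).
#' @export
positivity_threshold <- function(control_events, cytokine,
                                 percentile = 0.99, min_cells = 100) {
  if (nrow(control_events) < min_cells) {
    abort(paste0("too few control cells (", nrow(control_events), " < ",
                 min_cells, ") for a positivity threshold"),
          class = "cytoforge_threshold_error")
  }
  x <- control_events[[cytokine]]
  if (is.null(x)) abort(paste0("unknown cytokine marker '", cytokine, "'"))
  quantile(x, probs = percentile, type = 7, names = FALSE)
}

#' Percentage of cells above a positivity threshold
#'
#' @param events Cells of one population in one sample/condition.
#' @param cytokine Marker name.
#' @param threshold Positivity threshold; counts are strictly above.
#' @return Percentage in \[0, 100\].
#' @export
percent_positive <- function(events, cytokine, threshold) {
  x <- events[[cytokine]]
  if (is.null(x)) abort(paste0("unknown cytokine marker '", cytokine, "'"))
  if (length(x) == 0) return(NA_real_)
  100 * mean(x > threshold)
}

#' Quantify cytokine responses after TLR stimulation
#'
#' Re-clusters all (stimulated + control) samples on the 20-marker
#' stimulation set at `k` clusters, annotates clusters with the
#' stimulation-arm rule set (CD64 in place of Granzyme B), isolates each
#' responder population, gates each cytokine at the 99th percentile of the
#' matched population in the same patient's PBS control (pooled control
#' fallback when that population is too small), and scores percent-positive
#' cells per sample and condition.
#'
#' @param cohort A `cytof_cohort` simulated with `stimulated = TRUE`, or a
#'   named list of event tables with `.condition` columns.
#' @param populations Populations to score.
#' @param cytokines Cytokine markers.
#' @param k Clusters for the stimulation-arm clustering.
#' @param downsample_fraction,seed Passed to [spade_tree()].
#' @return A `stim_result` list: `scores` tibble `population, cytokine,
#'   patient, group, condition, percent_positive, threshold`, plus the
#'   `tree` and `annotation` used.
#' @export
stimulation_response <- function(cohort,
                                 populations = c("monocyte", "cdc", "pdc"),
                                 cytokines = c("MIP1b", "TNFa", "IL8"),
                                 k = 100, downsample_fraction = 0.05,
                                 seed = 1L) {
  samples <- if (inherits(cohort, "cytof_cohort")) cohort$samples else cohort
  conds <- unique(unlist(lapply(samples, function(s) unique(s$.condition))))
  if (!all(c("unstimulated", "TLR_stimulated") %in% conds)) {
    abort("paired stimulated and control samples are required")
  }
  tree <- spade_tree(samples, markers = stim20_markers(), k = k,
                     downsample_fraction = downsample_fraction, seed = seed)
  ranges <- marker_ranges(tree$events)
  categories <- categorize_clusters(tree, ranges)
  annotation <- annotate_clusters(categories,
                                  default_annotation_rules(stim = TRUE))
  ev <- tree$events
  ev$.cell_type <- annotation$cell_type[match(ev$.cluster,
                                              annotation$cluster)]
  scores <- list()
  for (pop in populations) {
    pop_cells <- ev[ev$.cell_type == pop, , drop = FALSE]
    control <- pop_cells[pop_cells$.condition == "unstimulated", ,
                         drop = FALSE]
    if (nrow(control) == 0) {
      warn(paste0("no control cells for population '", pop,
                  "'; skipping"))
      next
    }
    patients <- unique(pop_cells$.patient)
    for (cyt in cytokines) {
      pooled_thr <- positivity_threshold(control, cyt,
                                         min_cells = min(100, nrow(control)))
      for (pat in patients) {
        grp <- pop_cells$.group[pop_cells$.patient == pat][1]
        ctl_pat <- control[control$.patient == pat, , drop = FALSE]
        thr <- if (nrow(ctl_pat) >= 100) {
          positivity_threshold(ctl_pat, cyt)
        } else pooled_thr
        for (cond in c("unstimulated", "TLR_stimulated")) {
          cells <- pop_cells[pop_cells$.patient == pat &
                               pop_cells$.condition == cond, , drop = FALSE]
          scores[[length(scores) + 1]] <- tibble::tibble(
            population = pop, cytokine = cyt, patient = pat,
            group = grp, condition = cond,
            percent_positive = percent_positive(cells, cyt, thr),
            threshold = thr)
        }
      }
    }
  }
  structure(list(scores = dplyr::bind_rows(scores), tree = tree,
                 annotation = annotation),
            class = "stim_result")
}

#' @export
print.stim_result <- function(x, ...) {
  cat("<stim_result> ", nrow(x$scores), " population x cytokine x sample ",
      "scores\n", sep = "")
  invisible(x)
}

#' @rdname stimulation_response
#' @param x A `stim_result`.
#' @param ... Unused.
#' @export
tidy.stim_result <- function(x, ...) x$scores

#' Compare cytokine responses between conditions and groups
#'
#' Per population and cytokine: a permutation test of stimulated vs control
#' per-sample percent-positive values (patients lacking either condition are
#' excluded with a warning), and an RA-vs-healthy permutation test among
#' stimulated samples.
#'
#' @param result A `stim_result` (or its `scores` tibble).
#' @inheritParams permutation_test
#' @return A tibble `population, cytokine, p_stim_vs_control,
#'   p_ra_vs_healthy`.
#' @export
compare_response <- function(result, mode = c("auto", "exact",
                                              "monte_carlo"),
                             n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  scores <- if (inherits(result, "stim_result")) result$scores else result
  scores <- scores[!is.na(scores$percent_positive), , drop = FALSE]
  paired <- scores |>
    dplyr::group_by(.data$population, .data$cytokine, .data$patient) |>
    dplyr::filter(dplyr::n_distinct(.data$condition) == 2) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(scores$patient), unique(paired$patient))
  if (length(dropped) > 0) {
    warn(paste0("excluding unpaired sample(s): ",
                paste(dropped, collapse = ", ")))
  }
  paired |>
    dplyr::group_by(.data$population, .data$cytokine) |>
    dplyr::summarise(
      p_stim_vs_control = permutation_test(
        .data$percent_positive[.data$condition == "TLR_stimulated"],
        .data$percent_positive[.data$condition == "unstimulated"],
        mode = mode, n_perm = n_perm, seed = seed)$p_value,
      p_ra_vs_healthy = {
        st <- .data$condition == "TLR_stimulated"
        if (length(unique(.data$group[st])) == 2) {
          permutation_test(
            .data$percent_positive[st & .data$group == "RA"],
            .data$percent_positive[st & .data$group == "healthy"],
            mode = mode, n_perm = n_perm, seed = seed)$p_value
        } else NA_real_
      },
      .groups = "drop")
}
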