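# Subpopulation analysis: isolate an annotated cell population, embed it in
# two dimensions with t-SNE, delineate areas (polygons in embedding space or
# marker rules on the transformed scale), and quantify per-area percentages
# and marker mean signal intensities (MSI).

#' Isolate all cells of an annotated population
#'
#' Returns the cells assigned (via the clustering) to clusters carrying a
#' given cell-type annotation, provenance preserved.
#'
#' @param tree A [spade_tree()].
#' @param annotation Tibble `cluster, cell_type` from
#'   [annotate_clusters()].
#' @param cell_type Label to isolate, e.g. `"neutrophil"`.
#' @return Event table of the isolated cells (with `.cluster`).
#' @export
isolate_population <- function(tree, annotation, cell_type) {
  clusters <- annotation$cluster[annotation$cell_type == cell_type]
  if (length(clusters) == 0) {
    abort(paste0("no cluster is annotated '", cell_type, "'"),
          class = "cytoforge_empty_selection")
  }
  out <- tree$events[tree$events$.cluster %in% clusters, , drop = FALSE]
  set_events_transform(out, events_transform(tree$events),
                       attr(tree$events, "cofactor"))
}

#' t-SNE embedding of an isolated population
#'
#' Subsamples an equal number of cells from every sample, then embeds them
#' with t-SNE (Gaussian input affinities at the requested perplexity,
#' Student-t output kernel, exact gradients). Deterministic under the seed.
#'
#' @param events Event table with a `.sample_id` column.
#' @param markers Markers driving the embedding; the conventional choices
#'   are CD11b + CD16 for neutrophils and CD11a + CCR5 + Granzyme B for
#'   T-cells.
#' @param n_per_sample Equal per-sample cell count (clamped to the smallest
#'   sample).
#' @param perplexity t-SNE perplexity.
#' @param iterations Gradient-descent iterations.
#' @param seed Seed for subsampling and initialization.
#' @return A `cyto_embedding` tibble: the subsampled cells with `tsne1`,
#'   `tsne2` coordinates prepended; parameters in the `params` attribute.
#' @export
embed_cells <- function(events, markers, n_per_sample = 5000,
                        perplexity = 30, iterations = 1000, seed = 1L) {
  if (length(markers) == 0) abort("markers must be nonempty")
  samples <- split(events, events$.sample_id)
  sub <- dplyr::bind_rows(subsample_equal(samples, n_per_sample, seed = seed))
  if (nrow(sub) < 3 * perplexity + 1) {
    abort("too few cells for the requested perplexity")
  }
  coords <- cpp_tsne(event_matrix(sub, markers), perplexity,
                     as.integer(iterations), 200, derive_seed(seed, 23L))
  out <- dplyr::bind_cols(tibble::tibble(tsne1 = coords[, 1],
                                         tsne2 = coords[, 2]), sub)
  attr(out, "params") <- list(perplexity = perplexity,
                              iterations = iterations, seed = seed,
                              markers = markers)
  attr(out, "transform") <- events_transform(events)
  class(out) <- c("cyto_embedding", class(out))
  out
}

#' Define an analysis area
#'
#' Areas delineate subpopulations either as simple polygons in embedding
#' space or as marker rules on the transformed expression scale. Cells
#' matching no area fall into `"rest"`.
#'
#' @param name Area label.
#' @param x,y Polygon vertex coordinates in embedding space.
#' @return An `area_def` list.
#' @export
area_polygon <- function(name, x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("a polygon needs at least 3 (x, y) vertices")
  }
  structure(list(name = name, kind = "polygon", x = x, y = y),
            class = "area_def")
}

#' @rdname area_polygon
#' @param ... Named marker thresholds: `marker = c(">=", t)` or
#'   `marker = c("<=", t)`.
#' @export
area_rule <- function(name, ...) {
  conds <- list(...)
  if (length(conds) == 0) abort("a marker rule needs at least one condition")
  rules <- purrr::imap(conds, function(v, m) {
    if (length(v) != 2 || !v[1] %in% c(">=", "<=")) {
      abort("each condition must be c('>=', threshold) or c('<=', threshold)")
    }
    tibble::tibble(marker = m, comparator = v[1],
                   threshold = as.numeric(v[2]))
  })
  structure(list(name = name, kind = "marker_rule",
                 rules = dplyr::bind_rows(rules)),
            class = "area_def")
}

# Ray-casting point-in-polygon; points on an edge or vertex count as inside.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Assign every cell to an area
#'
#' Polygon areas are tested in embedding space (boundary counts as inside)
#' and must not overlap; marker-rule areas are tested on transformed
#' expression, first matching rule wins. Unmatched cells get `"rest"`.
#'
#' @param embedding A `cyto_embedding` (or any event table, for pure
#'   marker-rule definitions).
#' @param areas List of [area_polygon()] / [area_rule()] definitions.
#' @return The input with a `.area` column appended.
#' @export
assign_areas <- function(embedding, areas) {
  if (inherits(areas, "area_def")) areas <- list(areas)
  n <- nrow(embedding)
  hits <- matrix(FALSE, nrow = n, ncol = length(areas))
  for (a in seq_along(areas)) {
    def <- areas[[a]]
    if (def$kind == "polygon") {
      if (!all(c("tsne1", "tsne2") %in% names(embedding))) {
        abort("polygon areas need embedding coordinates (tsne1/tsne2)")
      }
      hits[, a] <- point_in_polygon(embedding$tsne1, embedding$tsne2,
                                    def$x, def$y)
    } else {
      ok <- rep(TRUE, n)
      for (i in seq_len(nrow(def$rules))) {
        v <- embedding[[def$rules$marker[i]]]
        if (is.null(v)) {
          abort(paste0("unknown marker '", def$rules$marker[i],
                       "' in area '", def$name, "'"))
        }
        ok <- ok & (if (def$rules$comparator[i] == ">=") {
          v >= def$rules$threshold[i]
        } else v <= def$rules$threshold[i])
      }
      hits[, a] <- ok
    }
  }
  poly <- which(vapply(areas, function(d) d$kind == "polygon", logical(1)))
  if (length(poly) > 1) {
    for (i in poly) for (j in poly[poly > i]) {
      if (any(hits[, i] & hits[, j])) {
        abort(paste0("overlapping polygon areas: '", areas[[i]]$name,
                     "' and '", areas[[j]]$name, "'"),
              class = "cytoforge_area_error")
      }
    }
  }
  label <- rep("rest", n)
  for (a in rev(seq_along(areas))) label[hits[, a]] <- areas[[a]]$name
  embedding$.area <- label
  embedding
}

#' Default marker-rule areas for the two planted subpopulations
#'
#' Thresholds sit midway between the simulator's parent and subpopulation
#' modes: CD11b <= 2.5 and CD16 >= 5 captures the CD11b-low CD16-high
#' neutrophil subset; CD11a >= 4.25 and Granzyme B >= 3.15 captures the
#' CD11a-high Granzyme-B-high T-cell subset.
#'
#' @param which `"neutrophil"` or `"t_cell"`.
#' @return A list of [area_rule()] definitions (the complement is
#'   `"rest"`-labelled, reported as Area 1).
#' @export
default_area_rules <- function(which = c("neutrophil", "t_cell")) {
  which <- match.arg(which)
  if (which == "neutrophil") {
    list(area_rule("Area 2", CD11b = c("<=", 2.5), CD16 = c(">=", 5)))
  } else {
    list(area_rule("Area 1", CD11a = c(">=", 4.25),
                   GranzymeB = c(">=", 3.15)))
  }
}

#' Per-sample and pooled area percentages with group comparison
#'
#' Computes, for every sample, the percentage of its cells in each area
#' (summing to 100), the pooled per-group percentages, and an RA-vs-healthy
#' permutation test per area on the per-sample percentages.
#'
#' @param events Event table with `.area`, `.sample_id`, `.group` columns.
#' @param expected_samples Optional vector of sample ids that should carry
#'   cells; samples absent from `events` (zero isolated cells) are excluded
#'   with a warning.
#' @inheritParams permutation_test
#' @return An `area_stats` list: `per_sample`, `pooled`, `tests`.
#' @export
area_percentages <- function(events, expected_samples = NULL,
                             mode = c("auto", "exact", "monte_carlo"),
                             n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (!".area" %in% names(events)) abort("run assign_areas() first")
  if (!is.null(expected_samples)) {
    empties <- setdiff(expected_samples, unique(events$.sample_id))
    if (length(empties) > 0) {
      warn(paste0("excluding sample(s) with no isolated cells: ",
                  paste(empties, collapse = ", ")))
    }
  }
  area_levels <- unique(events$.area)
  per_sample <- events |>
    dplyr::count(.data$.sample_id, .data$.group, .data$.area) |>
    dplyr::group_by(.data$.sample_id) |>
    tidyr::complete(.area = area_levels, fill = list(n = 0L)) |>
    dplyr::group_by(.data$.sample_id) |>
    dplyr::mutate(percentage = 100 * .data$n / sum(.data$n),
                  .group = .data$.group[!is.na(.data$.group)][1]) |>
    dplyr::ungroup() |>
    dplyr::select(sample_id = ".sample_id", group = ".group",
                  area = ".area", "n", "percentage")
  pooled <- events |>
    dplyr::count(.data$.group, .data$.area) |>
    dplyr::group_by(.data$.group) |>
    dplyr::mutate(percentage = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(group = ".group", area = ".area", "n", "percentage")
  tests <- per_sample |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(
      p_value = if (length(unique(.data$group)) == 2) {
        permutation_test(.data$percentage[.data$group == "RA"],
                         .data$percentage[.data$group == "healthy"],
                         mode = mode, n_perm = n_perm, seed = seed)$p_value
      } else NA_real_,
      .groups = "drop")
  structure(list(per_sample = per_sample, pooled = pooled, tests = tests),
            class = "area_stats")
}

#' @export
print.area_stats <- function(x, ...) {
  cat("<area_stats>\npooled percentages:\n")
  print(x$pooled)
  cat("RA vs healthy permutation p per area:\n")
  print(x$tests)
  invisible(x)
}

#' Mean signal intensity per area with pairwise permutation tests
#'
#' MSI is the mean transformed intensity of a marker over the cells of an
#' area. Pairwise between-area tests permute per-sample MSI values (the
#' sample, not the cell, is the independent unit).
#'
#' @param events Event table with `.area` and `.sample_id` columns.
#' @param marker Marker name.
#' @inheritParams permutation_test
#' @return A list: `msi` tibble `area, msi`, `per_sample` tibble, and
#'   `tests` tibble `area_a, area_b, p_value`.
#' @export
compare_msi <- function(events, marker, mode = c("auto", "exact",
                                                 "monte_carlo"),
                        n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (!marker %in% names(events)) {
    abort(paste0("unknown marker '", marker, "'"))
  }
  areas <- unique(events$.area)
  if (length(areas) < 2) abort("at least 2 populated areas required")
  msi <- events |>
    dplyr::group_by(area = .data$.area) |>
    dplyr::summarise(msi = mean(.data[[marker]]), .groups = "drop")
  per_sample <- events |>
    dplyr::group_by(area = .data$.area, sample_id = .data$.sample_id) |>
    dplyr::summarise(msi = mean(.data[[marker]]), .groups = "drop")
  pairs <- utils::combn(sort(areas), 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- per_sample$msi[per_sample$area == pairs[1, i]]
    b <- per_sample$msi[per_sample$area == pairs[2, i]]
    tibble::tibble(area_a = pairs[1, i], area_b = pairs[2, i],
                   p_value = permutation_test(a, b, mode = mode,
                                              n_perm = n_perm,
                                              seed = seed)$p_value)
  })
  list(msi = msi, per_sample = per_sample, tests = tests)
}

#' Scatter plot of an embedding
#'
#' @param object A `cyto_embedding`.
#' @param colour Column to colour by (`".group"`, `".area"`, or a marker
#'   name).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_embedding <- function(object, colour = ".group", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                       colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}
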