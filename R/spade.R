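# SPADE-style clustering: density-dependent downsampling, agglomerative
# clustering of the downsampled pool, a minimum spanning tree over cluster
# medians, and upsampling of every cell to its nearest cluster median. All
# distances are L1 (city block) over the chosen clustering-marker set.

#' Estimate per-cell local density
#'
#' The density of a cell is the number of cells (itself included) within an
#' L1 distance of `alpha` times the median nearest-neighbour distance of a
#' seeded subsample, over the clustering markers.
#'
#' @param events Transformed event table.
#' @param markers Clustering markers (character vector).
#' @param alpha Kernel width multiplier (positive); 5 by default.
#' @param nn_subsample Subsample size used to estimate the median
#'   nearest-neighbour distance.
#' @param seed Seed for the nearest-neighbour subsample.
#' @return A list (class `cyto_density`) with `density` (per-cell counts,
#'   all >= 1), `radius`, and `median_nn_dist`.
#' @export
estimate_density <- function(events, markers = marker_cols(events),
                             alpha = 5, nn_subsample = 2000, seed = 1L) {
  if (nrow(events) < 2) abort("density estimation needs at least 2 cells")
  if (length(markers) == 0) abort("markers must be nonempty")
  if (alpha <= 0) abort("alpha must be positive")
  x <- event_matrix(events, markers)
  set.seed(derive_seed(seed, 7L))
  idx <- if (nrow(x) > nn_subsample) {
    sort(sample.int(nrow(x), nn_subsample))
  } else seq_len(nrow(x))
  d_med <- median(cpp_l1_nn_dist(x[idx, , drop = FALSE]))
  radius <- alpha * d_med
  structure(list(density = cpp_l1_density(x, radius), radius = radius,
                 median_nn_dist = d_med, alpha = alpha, metric = "L1",
                 n_cells = nrow(x)),
            class = "cyto_density")
}

# Target density TD such that mean(pmin(1, TD / density)) hits the target
# retained fraction, found by bisection.
solve_target_density <- function(density, target_fraction, tol = 0.002) {
  f <- function(td) mean(pmin(1, td / density))
  lo <- 0
  hi <- max(density)
  if (f(hi) <= target_fraction) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid) - target_fraction) < tol / 10) return(mid)
    if (f(mid) < target_fraction) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Density-dependent downsampling
#'
#' Retains each cell with probability `min(1, TD / density)`, where the
#' target density TD is solved by bisection so the expected retained
#' fraction equals `target_fraction`. Dense regions are thinned while rare
#' cells are kept, equalizing density across phenotypic space.
#'
#' @param events Event table aligned with `density`.
#' @param density A `cyto_density` from [estimate_density()] (or a numeric
#'   vector of per-cell densities).
#' @param target_fraction Expected retained fraction in (0, 1].
#' @param seed Seed for the retention draws.
#' @return The retained subset of `events` (attributes preserved).
#' @export
downsample_events <- function(events, density, target_fraction = 0.05,
                              seed = 1L) {
  d <- if (inherits(density, "cyto_density")) density$density else density
  if (length(d) != nrow(events)) abort("density is not aligned with events")
  if (target_fraction <= 0 || target_fraction > 1) {
    abort("target_fraction must be in (0, 1]")
  }
  if (target_fraction == 1) return(events)
  td <- solve_target_density(d, target_fraction)
  set.seed(derive_seed(seed, 11L))
  keep <- runif(length(d)) < pmin(1, td / d)
  out <- events[keep, , drop = FALSE]
  set_events_transform(out, events_transform(events), attr(events, "cofactor"))
}

#' Agglomerative clustering of downsampled cells
#'
#' Average-linkage hierarchical clustering on L1 distances over the
#' clustering markers, cut at `k` clusters.
#'
#' @param events Downsampled event table with at least `k` cells.
#' @param markers Clustering markers.
#' @param k Number of clusters.
#' @return A list with `assignment` (per-cell cluster id 1..k) and `medians`
#'   (k x markers matrix of per-cluster medians).
#' @export
cluster_cells <- function(events, markers = marker_cols(events), k) {
  x <- event_matrix(events, markers)
  if (k > nrow(x)) abort("k exceeds the number of cells")
  hc <- hclust(dist(x, method = "manhattan"), method = "average")
  assignment <- cutree(hc, k = k)
  medians <- cluster_medians(x, assignment, k)
  list(assignment = assignment, medians = medians)
}

cluster_medians <- function(x, assignment, k) {
  med <- matrix(NA_real_, nrow = k, ncol = ncol(x),
                dimnames = list(seq_len(k), colnames(x)))
  for (c in seq_len(k)) {
    idx <- which(assignment == c)
    if (length(idx) > 0) {
      med[c, ] <- apply(x[idx, , drop = FALSE], 2, median)
    }
  }
  med
}

#' Minimum spanning tree over cluster medians
#'
#' Builds the MST of the complete graph on cluster medians with L1 edge
#' weights.
#'
#' @param medians Clusters x markers matrix (rownames are cluster ids).
#' @return A tibble `from, to, weight` with k - 1 rows spanning all
#'   clusters.
#' @export
build_mst <- function(medians) {
  medians <- medians[stats::complete.cases(medians), , drop = FALSE]
  if (nrow(medians) < 2) abort("an MST needs at least 2 clusters")
  ids <- rownames(medians) %||% as.character(seq_len(nrow(medians)))
  if (anyDuplicated(ids)) abort("duplicate cluster ids")
  dmat <- as.matrix(dist(medians, method = "manhattan"))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mst, names = FALSE)
  tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]],
                 weight = igraph::E(mst)$weight)
}

#' Assign every cell to its nearest cluster median
#'
#' L1 nearest-median assignment over the clustering markers; ties resolve to
#' the lower cluster id.
#'
#' @param events Full event table.
#' @param medians Clusters x markers matrix from [cluster_cells()].
#' @param markers Clustering markers (must match the median columns).
#' @return Integer vector of cluster ids.
#' @export
upsample_cells <- function(events, medians, markers = colnames(medians)) {
  x <- event_matrix(events, markers)
  ok <- stats::complete.cases(medians)
  m <- medians[ok, markers, drop = FALSE]
  ids <- which(ok)
  ids[cpp_l1_nn_assign(x, m)]
}

#' Per-cluster, per-sample abundance fractions
#'
#' @param events Event table with `.sample_id` and `.cluster` columns.
#' @param k Total number of clusters (empty clusters kept at zero
#'   abundance).
#' @return A tibble `cluster, sample_id, n, fraction`; fractions sum to 1
#'   within each sample.
#' @export
cluster_abundance <- function(events, k = max(events$.cluster)) {
  counts <- events |>
    dplyr::count(.data$.sample_id, .data$.cluster) |>
    tidyr::complete(.sample_id = unique(events$.sample_id),
                    .cluster = seq_len(k), fill = list(n = 0L)) |>
    dplyr::group_by(.data$.sample_id) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  dplyr::select(counts, cluster = ".cluster", sample_id = ".sample_id",
                "n", "fraction")
}

#' Run the full SPADE-style clustering stage
#'
#' Per sample: estimate density and downsample to `downsample_fraction`.
#' Pooled: agglomerative clustering (average linkage, L1) of the
#' downsampled cells cut at `k`, MST over pooled cluster medians, then
#' upsampling of every cell of every sample to its nearest cluster median.
#'
#' @param samples Named list of transformed event tables (or a
#'   `cytof_cohort`).
#' @param markers Clustering markers.
#' @param k Number of clusters (500 for the main analysis arm, 100 for the
#'   stimulation arm).
#' @param downsample_fraction Target retained fraction per sample.
#' @param alpha Density kernel width multiplier.
#' @param density_floor_pct Optional percentile in (0, 100); cells below
#'   this density percentile are dropped as outliers before downsampling
#'   (off by default).
#' @param seed Seed controlling downsampling and tie-free reproducibility.
#' @return A `spade_tree`: `events` (all cells with `.cluster`),
#'   `medians_long` (cluster x sample x marker medians over all markers),
#'   `pooled_medians`, `mst`, `abundance`, `k`, `markers`, `params`.
#' @export
spade_tree <- function(samples, markers, k = 500,
                       downsample_fraction = 0.05, alpha = 5,
                       density_floor_pct = NULL, seed = 1L) {
  if (inherits(samples, "cytof_cohort")) samples <- samples$samples
  sub_list <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    dens <- estimate_density(samples[[i]], markers, alpha = alpha,
                             seed = derive_seed(seed, i))
    ev <- samples[[i]]
    d <- dens$density
    if (!is.null(density_floor_pct)) {
      floor_d <- quantile(d, density_floor_pct / 100)
      keep <- d >= floor_d
      ev <- ev[keep, , drop = FALSE]
      d <- d[keep]
    }
    sub_list[[i]] <- downsample_events(ev, d, downsample_fraction,
                                       seed = derive_seed(seed, 1000L + i))
    sub_list[[i]] <- set_events_transform(sub_list[[i]],
                                          events_transform(samples[[i]]),
                                          attr(samples[[i]], "cofactor"))
  }
  sub <- dplyr::bind_rows(sub_list)
  fit <- cluster_cells(sub, markers, k)
  full <- dplyr::bind_rows(samples)
  full$.cluster <- upsample_cells(full, fit$medians, markers)

  all_markers <- marker_cols(full)
  medians_long <- full |>
    dplyr::group_by(.data$.cluster, .data$.sample_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(all_markers), median),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(all_markers), names_to = "marker",
                        values_to = "median") |>
    dplyr::rename(cluster = ".cluster", sample_id = ".sample_id")

  pooled <- cluster_medians(event_matrix(full, all_markers), full$.cluster, k)
  empty <- which(!seq_len(k) %in% unique(full$.cluster))
  if (length(empty) > 0) {
    warn(paste0(length(empty), " cluster(s) empty after upsampling; ",
                "retained with zero abundance"))
  }
  structure(list(
    events = full, k = k, markers = markers,
    medians_long = medians_long, pooled_medians = pooled,
    mst = build_mst(pooled[, markers, drop = FALSE]),
    abundance = cluster_abundance(full, k),
    empty_clusters = empty,
    params = list(downsample_fraction = downsample_fraction, alpha = alpha,
                  density_floor_pct = density_floor_pct, seed = seed)
  ), class = "spade_tree")
}

#' @export
print.spade_tree <- function(x, ...) {
  cat("<spade_tree> k = ", x$k, ", ", nrow(x$events), " cells, ",
      length(unique(x$events$.sample_id)), " samples, ",
      length(x$markers), " clustering markers\n", sep = "")
  invisible(x)
}

#' @rdname spade_tree
#' @param x A `spade_tree`.
#' @param ... Unused.
#' @export
tidy.spade_tree <- function(x, ...) x$abundance

#' @rdname spade_tree
#' @export
glance.spade_tree <- function(x, ...) {
  tibble::tibble(k = x$k, n_cells = nrow(x$events),
                 n_samples = length(unique(x$events$.sample_id)),
                 n_empty_clusters = length(x$empty_clusters),
                 mst_weight = sum(x$mst$weight))
}
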