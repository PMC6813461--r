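# Categorical phenotyping: per-marker expression ranges from the pooled
# cells, five uniform categories over the 5th-95th percentile range, and
# rule-based cell-type annotation of clusters.

#' Per-marker 5th/95th percentile expression ranges
#'
#' Percentiles use the linear-interpolation quantile definition and are
#' computed over all pooled cells.
#'
#' @param events Pooled, transformed event table.
#' @param markers Markers to range; defaults to all marker columns.
#' @return A tibble `marker, p5, p95`.
#' @export
marker_ranges <- function(events, markers = marker_cols(events)) {
  x <- event_matrix(events, markers)
  tibble::tibble(
    marker = markers,
    p5 = unname(apply(x, 2, quantile, probs = 0.05, type = 7,
                      names = FALSE)),
    p95 = unname(apply(x, 2, quantile, probs = 0.95, type = 7,
                       names = FALSE))
  )
}

# Left-closed/right-open bins over [p5, p95] (last bin closed); values
# outside the range clamp to the extreme categories 0 and 4. A degenerate
# range (p5 == p95) maps in-range values to the middle category.
bin_category <- function(v, p5, p95) {
  n <- max(length(v), length(p5), length(p95))
  v <- rep_len(v, n)
  p5 <- rep_len(p5, n)
  p95 <- rep_len(p95, n)
  w <- (p95 - p5) / 5
  mid <- rep(2L, n)
  pos <- w > 0
  mid[pos] <- pmin(4L, as.integer(floor((v[pos] - p5[pos]) / w[pos])))
  out <- rep(NA_integer_, n)
  ok <- !is.na(v)
  out[ok] <- ifelse(v[ok] < p5[ok], 0L,
                    ifelse(v[ok] > p95[ok], 4L, mid[ok]))
  out
}

#' Categorize cluster phenotypes into five levels
#'
#' For each cluster and marker the representative value is the mean over
#' samples of the per-(cluster, sample) expression medians (samples in which
#' the cluster is empty do not contribute). The marker's 5th-95th percentile
#' range is split into five uniform categories — negative (0), low, medium,
#' high, bright (4) — with left-closed binning and clamping outside the
#' range.
#'
#' @param tree A [spade_tree()].
#' @param ranges Tibble from [marker_ranges()].
#' @return A `cyto_phenotype`: tibble `cluster, marker, value, category`
#'   (clusters empty in every sample carry `NA` and are flagged in the
#'   `missing_clusters` attribute).
#' @export
categorize_clusters <- function(tree, ranges) {
  values <- tree$medians_long |>
    dplyr::group_by(.data$cluster, .data$marker) |>
    dplyr::summarise(value = mean(.data$median), .groups = "drop")
  grid <- tidyr::expand_grid(cluster = seq_len(tree$k),
                             marker = ranges$marker) |>
    dplyr::left_join(values, by = c("cluster", "marker")) |>
    dplyr::left_join(ranges, by = "marker") |>
    dplyr::mutate(category = bin_category(.data$value, .data$p5, .data$p95)) |>
    dplyr::select("cluster", "marker", "value", "category")
  missing <- setdiff(seq_len(tree$k), unique(values$cluster))
  attr(grid, "missing_clusters") <- missing
  attr(grid, "ranges") <- ranges
  class(grid) <- c("cyto_phenotype", class(grid))
  grid
}

phenotype_matrix <- function(categories) {
  wide <- tidyr::pivot_wider(
    categories[, c("cluster", "marker", "category")],
    names_from = "marker", values_from = "category")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cluster
  m
}

#' Heatmap leaf orders from hierarchical clustering of category vectors
#'
#' Average-linkage hierarchical clustering on Euclidean distances of the
#' category vectors; clusters are ordered by one dendrogram, clustering
#' markers and the remaining markers by two separate dendrograms.
#'
#' @param categories A `cyto_phenotype`.
#' @param clustering_markers Markers used for clustering (ordered
#'   separately); `NULL` orders all markers together.
#' @return A list `cluster_order`, `marker_order_clustering`,
#'   `marker_order_other`.
#' @export
order_heatmap <- function(categories, clustering_markers = NULL) {
  m <- phenotype_matrix(categories)
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  leaf_order <- function(x) {
    if (nrow(x) < 2) return(rownames(x))
    hc <- hclust(dist(x, method = "euclidean"), method = "average")
    rownames(x)[hc$order]
  }
  clustering_markers <- clustering_markers %||% colnames(m)
  other <- setdiff(colnames(m), clustering_markers)
  list(
    cluster_order = leaf_order(m),
    marker_order_clustering = leaf_order(t(m[, clustering_markers,
                                             drop = FALSE])),
    marker_order_other = if (length(other) > 1) {
      leaf_order(t(m[, other, drop = FALSE]))
    } else other
  )
}

#' Default cell-type annotation rules
#'
#' Category-scale (0-4) rules over the nine annotation markers, applied in
#' priority order; the first matching rule labels the cluster. The
#' stimulation-arm variant uses CD64 in place of Granzyme B.
#'
#' @param stim Use the stimulation-arm marker set.
#' @return A tibble `priority, cell_type, marker, comparator, threshold`
#'   (comparator `"ge"` or `"le"`).
#' @export
default_annotation_rules <- function(stim = FALSE) {
  r <- function(priority, cell_type, ...) {
    v <- c(...)
    comp <- ifelse(startsWith(names(v), "le_"), "le", "ge")
    tibble::tibble(priority = priority, cell_type = cell_type,
                   marker = sub("^le_", "", names(v)),
                   comparator = comp, threshold = unname(v))
  }
  rules <- dplyr::bind_rows(
    r(1, "neutrophil", CD66 = 3),
    r(2, "t_cell", CD3 = 3, le_CD66 = 1),
    r(3, "b_cell", CD19 = 3),
    r(4, "pdc", CD123 = 3, HLADR = 3),
    r(5, "basophil", CD123 = 3, le_HLADR = 1),
    r(6, "monocyte", CD14 = 3),
    r(7, "nk", CD16 = 3, le_CD3 = 1, le_CD66 = 1),
    r(8, "cdc", CD11c = 3, HLADR = 3, le_CD14 = 1)
  )
  if (stim) rules$marker[rules$marker == "GranzymeB"] <- "CD64"
  rules
}

validate_rules <- function(rules, markers) {
  unknown <- setdiff(rules$marker, markers)
  if (length(unknown) > 0) {
    abort(paste0("annotation rule references unknown marker(s): ",
                 paste(unknown, collapse = ", ")))
  }
  bad <- rules |>
    dplyr::group_by(.data$cell_type, .data$marker) |>
    dplyr::summarise(
      contradictory = any(.data$comparator == "ge") &&
        any(.data$comparator == "le") &&
        max(.data$threshold[.data$comparator == "ge"]) >
          min(.data$threshold[.data$comparator == "le"]),
      .groups = "drop") |>
    dplyr::filter(.data$contradictory)
  if (nrow(bad) > 0) {
    abort(paste0("contradictory rule for ", bad$cell_type[1], "/",
                 bad$marker[1], ": incompatible bounds"),
          class = "cytoforge_rule_error")
  }
  invisible(rules)
}

#' Annotate clusters with cell-type labels by rule
#'
#' Each cluster is tested against the rule set in priority order; the first
#' cell type whose requirements (category comparisons) all hold labels the
#' cluster. Clusters matching no rule are `"unassigned"`.
#'
#' @param categories A `cyto_phenotype`.
#' @param rules Rule tibble as from [default_annotation_rules()].
#' @return A tibble `cluster, cell_type`.
#' @export
annotate_clusters <- function(categories, rules = default_annotation_rules()) {
  validate_rules(rules, unique(categories$marker))
  m <- phenotype_matrix(categories)
  labels <- rep("unassigned", nrow(m))
  for (p in sort(unique(rules$priority))) {
    rr <- rules[rules$priority == p, ]
    ok <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(rr))) {
      cat <- m[, rr$marker[i]]
      hit <- if (rr$comparator[i] == "ge") cat >= rr$threshold[i]
             else cat <= rr$threshold[i]
      ok <- ok & !is.na(hit) & hit
    }
    labels[ok & labels == "unassigned"] <- rr$cell_type[1]
  }
  tibble::tibble(cluster = as.integer(rownames(m)), cell_type = labels)
}

#' Heatmap of categorical cluster phenotypes
#'
#' Five-level white-to-dark-red tile map of cluster x marker categories,
#' with rows and columns ordered by [order_heatmap()].
#'
#' @param object A `cyto_phenotype`.
#' @param clustering_markers Optional marker subset ordered separately from
#'   the rest.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_phenotype <- function(object, clustering_markers = NULL, ...) {
  ord <- order_heatmap(object, clustering_markers)
  df <- object |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::mutate(
      cluster = factor(.data$cluster, levels = ord$cluster_order),
      marker = factor(.data$marker,
                      levels = c(ord$marker_order_clustering,
                                 ord$marker_order_other)),
      level = factor(.data$category, levels = 0:4,
                     labels = c("negative", "low", "medium", "high",
                                "bright")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$cluster,
                                   fill = .data$level)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(negative = "#FFFFFF", low = "#FDD0A2", medium = "#FC8D59",
                 high = "#D7301F", bright = "#7F0000"),
      drop = FALSE, name = "relative\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "cluster")
}
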