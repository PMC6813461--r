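# Differential cluster abundance: enrichment trends by group means and a
# non-parametric group-label permutation test on per-sample abundance
# fractions.

#' Two-sample permutation test on group means
#'
#' Statistic: absolute difference of group means. Exact mode enumerates all
#' distinct relabelings (all size-`length(x)` subsets of the pooled values);
#' Monte-Carlo mode draws `n_perm` random relabelings. The p-value counts
#' relabelings whose statistic is at least the observed one, the identity
#' relabeling included, so p is always positive and `p >= 1 / total`.
#'
#' @param x,y Numeric group samples (each nonempty).
#' @param mode `"auto"` (exact when `choose(n, length(x)) <= 1e6`, otherwise
#'   Monte-Carlo), `"exact"`, or `"monte_carlo"`.
#' @param n_perm Number of random relabelings in Monte-Carlo mode.
#' @param seed Seed for Monte-Carlo mode.
#' @return A `perm_test` list: `statistic`, `p_value`, `mode`,
#'   `n_relabelings`.
#' @export
permutation_test <- function(x, y, mode = c("auto", "exact", "monte_carlo"),
                             n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1) abort("both groups must be nonempty")
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  n_exact <- choose(n, nx)
  if (mode == "auto") mode <- if (n_exact <= 1e6) "exact" else "monte_carlo"
  if (mode == "exact" && n_exact > 1e6) {
    abort(paste0("exact enumeration over ", format(n_exact, big.mark = ","),
                 " relabelings refused; use mode = 'monte_carlo'"))
  }
  tol <- 1e-12 * (1 + obs)
  if (mode == "exact") {
    combos <- combn(n, nx)
    total_sum <- sum(pooled)
    gsum <- colSums(matrix(pooled[combos], nrow = nx))
    stats <- abs(gsum / nx - (total_sum - gsum) / (n - nx))
    count <- sum(stats >= obs - tol)
    p <- count / ncol(combos)
    n_rel <- ncol(combos)
  } else {
    set.seed(derive_seed(seed, 13L))
    count <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, nx)
      s <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
      if (s >= obs - tol) count <- count + 1L
    }
    p <- (count + 1) / (n_perm + 1)  # identity relabeling included
    n_rel <- n_perm + 1
  }
  structure(list(statistic = obs, p_value = p, mode = mode,
                 n_relabelings = n_rel),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (|difference of means|): stat = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4),
      " (", x$mode, ", ", x$n_relabelings, " relabelings)\n", sep = "")
  invisible(x)
}

#' @rdname permutation_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 mode = x$mode, n_relabelings = x$n_relabelings)
}

sample_groups <- function(abundance, groups) {
  if (is.data.frame(groups)) {
    g <- setNames(groups$group, groups$sample_id %||% groups$patient)
  } else g <- groups
  ids <- unique(abundance$sample_id)
  missing <- setdiff(ids, names(g))
  if (length(missing) > 0) {
    abort(paste0("group label missing for sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  g[ids]
}

#' Per-cluster enrichment trend (RA vs healthy)
#'
#' A cluster trends RA-enriched when its mean abundance fraction over RA
#' samples exceeds the mean over healthy samples, healthy-enriched in the
#' opposite case, and tied on exact equality.
#'
#' @param abundance Tibble `cluster, sample_id, fraction` (e.g.
#'   `tidy(tree)`).
#' @param groups Named vector or tibble mapping sample ids to
#'   `"RA"`/`"healthy"`.
#' @return A tibble `cluster, mean_ra, mean_healthy, trend`.
#' @export
enrichment_trend <- function(abundance, groups) {
  g <- sample_groups(abundance, groups)
  if (!all(c("RA", "healthy") %in% g)) abort("both groups must be nonempty")
  abundance |>
    dplyr::mutate(group = unname(g[.data$sample_id])) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      mean_ra = mean(.data$fraction[.data$group == "RA"]),
      mean_healthy = mean(.data$fraction[.data$group == "healthy"]),
      .groups = "drop") |>
    dplyr::mutate(trend = dplyr::case_when(
      .data$mean_ra > .data$mean_healthy ~ "RA-enriched",
      .data$mean_ra < .data$mean_healthy ~ "healthy-enriched",
      TRUE ~ "tied"))
}

#' Differential cluster abundance testing
#'
#' Combines the enrichment trend with a per-cluster permutation test of the
#' per-sample abundance fractions between groups.
#'
#' @inheritParams enrichment_trend
#' @inheritParams permutation_test
#' @param alpha Significance level.
#' @param p_adjust Apply Benjamini-Hochberg adjustment before flagging
#'   significance (off by default).
#' @return A tibble `cluster, mean_ra, mean_healthy, trend, p_value,
#'   significant` (plus `p_adjusted` when `p_adjust = TRUE`).
#' @export
test_abundance <- function(abundance, groups,
                           mode = c("auto", "exact", "monte_carlo"),
                           n_perm = 10000, alpha = 0.05, p_adjust = FALSE,
                           seed = 1L) {
  mode <- match.arg(mode)
  g <- sample_groups(abundance, groups)
  trends <- enrichment_trend(abundance, groups)
  pvals <- abundance |>
    dplyr::mutate(group = unname(g[.data$sample_id])) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      p_value = permutation_test(.data$fraction[.data$group == "RA"],
                                 .data$fraction[.data$group == "healthy"],
                                 mode = mode, n_perm = n_perm,
                                 seed = seed)$p_value,
      .groups = "drop")
  out <- dplyr::left_join(trends, pvals, by = "cluster")
  if (p_adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' Summarize enrichment trends by cell type
#'
#' Reports, per annotated cell type, the fraction of all clusters it
#' accounts for and the fraction of its clusters trending RA-enriched, plus
#' the overall RA-enriched fraction.
#'
#' @param trends Output of [enrichment_trend()] or [test_abundance()].
#' @param annotation Tibble `cluster, cell_type` from
#'   [annotate_clusters()].
#' @return A list: `by_cell_type` tibble `cell_type, n_clusters,
#'   fraction_of_clusters, fraction_ra_enriched` and `overall_ra_enriched`.
#' @export
summarize_enrichment <- function(trends, annotation) {
  joined <- dplyr::left_join(trends, annotation, by = "cluster")
  if (anyNA(joined$cell_type)) {
    abort("annotation must cover every cluster in the trend table")
  }
  by_type <- joined |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      fraction_ra_enriched = mean(.data$trend == "RA-enriched"),
      .groups = "drop") |>
    dplyr::mutate(fraction_of_clusters = .data$n_clusters /
                    sum(.data$n_clusters)) |>
    dplyr::select("cell_type", "n_clusters", "fraction_of_clusters",
                  "fraction_ra_enriched")
  list(by_cell_type = by_type,
       overall_ra_enriched = mean(joined$trend == "RA-enriched"))
}
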