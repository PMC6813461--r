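# Clinical correlation: Spearman rank correlation with an exact
# enumeration-based p-value for small tie-free samples and the Student-t
# approximation otherwise, plus treatment-group comparisons via the
# permutation test.

#' Spearman rank correlation with exact or t-approximate p-value
#'
#' The coefficient is the Pearson correlation of (mid-)ranks. When neither
#' vector has ties and `n <= exact_limit`, the two-sided p-value comes from
#' the exact permutation null of the rank statistic S (sum of squared rank
#' differences), enumerated over all n! rank orders:
#' `p = min(1, 2 * min(P(S <= s), P(S >= s)))`. Otherwise the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` against Student's
#' t with n - 2 degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length n >= 3 with no missing
#'   values.
#' @param exact_limit Largest n for which the exact null is enumerated.
#' @return A `spearman_test` list: `rho`, `p_value`, `method`
#'   (`"exact_enumeration"` or `"t_approximation"`), `n`, `ties_present`,
#'   `statistic` (S in exact mode, t otherwise).
#' @export
spearman_test <- function(x, y, exact_limit = 10) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3) abort("at least 3 observations required")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("correlation undefined for a constant input vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= exact_limit) {
    s <- sum((rx - ry)^2)
    counts <- cpp_spearman_s_counts(n)
    total <- sum(counts)
    s_values <- seq_along(counts) - 1
    lower <- sum(counts[s_values <= s]) / total
    upper <- sum(counts[s_values >= s]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact_enumeration"
    stat <- s
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(stat), df = n - 2)
    method <- "t_approximation"
  }
  structure(list(rho = rho, p_value = p, method = method, n = n,
                 ties_present = ties, statistic = stat),
            class = "spearman_test")
}

#' Spearman p-value from a reported coefficient
#'
#' Computes the two-sided p-value for a given Spearman coefficient and
#' sample size without the raw data: either the t-approximation (the method
#' forced whenever ties are present) or the exact enumeration null (the
#' coefficient must then correspond to an attainable tie-free rank
#' statistic).
#'
#' @param rho Spearman correlation coefficient in \[-1, 1\].
#' @param n Sample size (>= 3).
#' @param method `"t_approximation"` or `"exact_enumeration"`.
#' @return Two-sided p-value.
#' @export
spearman_p_value <- function(rho, n,
                             method = c("t_approximation",
                                        "exact_enumeration")) {
  method <- match.arg(method)
  if (abs(rho) > 1) abort("rho must be in [-1, 1]")
  if (n < 3) abort("n must be >= 3")
  if (method == "t_approximation") {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(-abs(t), df = n - 2))
  }
  # rho = 1 - 6 S / (n (n^2 - 1)) for tie-free ranks
  s <- round((1 - rho) * n * (n^2 - 1) / 6)
  counts <- cpp_spearman_s_counts(n)
  total <- sum(counts)
  s_values <- seq_along(counts) - 1
  min(1, 2 * min(sum(counts[s_values <= s]) / total,
                 sum(counts[s_values >= s]) / total))
}

#' @export
print.spearman_test <- function(x, ...) {
  cat("Spearman correlation: rho = ", signif(x$rho, 4), ", p = ",
      signif(x$p_value, 4), " (", x$method,
      if (x$ties_present) ", ties" else "", ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @rdname spearman_test
#' @export
tidy.spearman_test <- function(x, ...) {
  tibble::tibble(estimate = x$rho, statistic = x$statistic,
                 p.value = x$p_value, method = x$method, n = x$n,
                 ties_present = x$ties_present,
                 covariate = attr(x, "covariate") %||% NA_character_)
}

#' Correlate subpopulation abundance with a clinical covariate
#'
#' Joins per-sample subpopulation percentages to the clinical table,
#' restricts to RA patients (healthy donors carry no clinical covariates),
#' and runs [spearman_test()] against the chosen covariate.
#'
#' @param subpop_pct Tibble with `patient` (or `sample_id`) and `value`
#'   columns.
#' @param clinical Clinical table as from [simulate_clinical()].
#' @param covariate `"duration_months"` or `"das28"`.
#' @return A `spearman_test` annotated with the covariate name.
#' @export
correlate_abundance <- function(subpop_pct, clinical,
                                covariate = c("duration_months", "das28")) {
  covariate <- match.arg(covariate)
  if (!"patient" %in% names(subpop_pct)) {
    subpop_pct <- dplyr::rename(subpop_pct, patient = "sample_id")
  }
  ra <- clinical[clinical$group == "RA", ]
  joined <- dplyr::inner_join(subpop_pct, ra, by = "patient")
  if (nrow(joined) != sum(subpop_pct$patient %in% ra$patient)) {
    abort("subpopulation percentages do not align with RA patients")
  }
  res <- spearman_test(joined$value, joined[[covariate]])
  attr(res, "covariate") <- covariate
  res
}

#' Read a clinical covariate table
#'
#' Reads a patient table in the conventional column layout
#' (`Patients`, `Age range (years)`, `Current treatments`,
#' `Disease duration (months)`, `DAS28`, `Anti-CCP`, `Erosion`, `RF`) and
#' maps it to the internal names used throughout the package. The shipped
#' reference fixture lives at
#' `system.file("extdata", "clinical_table1.csv", package = "cytoforge")`.
#'
#' @param path CSV path.
#' @param group Group label assigned to the rows (`"RA"` by default).
#' @return A tibble matching [simulate_clinical()]'s layout.
#' @export
read_clinical <- function(path, group = "RA") {
  df <- read.csv(path, check.names = FALSE)
  wanted <- c("Patients", "Age range (years)", "Current treatments",
              "Disease duration (months)", "DAS28", "Anti-CCP", "Erosion",
              "RF")
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0) {
    abort(paste0("clinical table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    patient = as.character(df$Patients), group = group,
    age_range = df[["Age range (years)"]],
    treatments = df[["Current treatments"]],
    duration_months = as.integer(df[["Disease duration (months)"]]),
    das28 = as.numeric(df$DAS28),
    anti_ccp = as.character(df[["Anti-CCP"]]),
    erosion = as.character(df$Erosion), rf = as.character(df$RF))
}

#' Compare subpopulation abundance between two groups
#'
#' Exact permutation test (difference of group means) on per-sample
#' percentages, e.g. methotrexate-treated vs other patients or
#' patient-subgroup vs healthy donors.
#'
#' @param values Per-sample numeric values.
#' @param groups Per-sample group labels (exactly two distinct).
#' @inheritParams permutation_test
#' @return A `perm_test`.
#' @export
compare_groups <- function(values, groups,
                           mode = c("auto", "exact", "monte_carlo"),
                           n_perm = 10000, seed = 1L) {
  lev <- unique(groups)
  if (length(lev) != 2) abort("exactly two groups required")
  permutation_test(values[groups == lev[1]], values[groups == lev[2]],
                   mode = match.arg(mode), n_perm = n_perm, seed = seed)
}
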