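#' Average pesticide dosage
#'
#' Annual pesticide usage divided by annual agricultural production,
#' expressed in kg of pesticide per ton of produce.
#'
#' @param usage_t Pesticide usage in tons per year.
#' @param production_t Agricultural production in tons per year (must be
#'   positive).
#' @return Dosage in kg/ton (vectorised).
#' @export
#' @examples
#' pesticide_dosage(2, 1000) # 2 kg per ton
pesticide_dosage <- function(usage_t, production_t) {
  if (any(is.na(production_t)) || any(production_t <= 0)) {
    abort("production_t must be positive")
  }
  if (any(usage_t < 0, na.rm = TRUE)) {
    abort("usage_t must be non-negative")
  }
  usage_t * 1000 / production_t
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-sided p-value uses
#' the exact permutation distribution for n of 10 or fewer (small
#' provincial comparisons need exactness) and the t-approximation
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with `rho` and `p_value`.
#' @export
#' @examples
#' rank_correlation(1:5, c(2, 1, 4, 3, 5))
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Correlation is undefined for a constant vector")
  }
  n <- length(x)
  exact <- n <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "two.sided", exact = exact)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Rank-based difference test between groups
#'
#' Two groups are compared with the Mann-Whitney U test, three or more with
#' the Kruskal-Wallis test; both two-sided and tie-corrected.
#'
#' @param groups List of numeric vectors, each non-empty, at least two.
#' @return List with `statistic`, `p_value`, and `method`
#'   (`"mann_whitney"` or `"kruskal_wallis"`).
#' @export
#' @examples
#' group_difference(list(c(1, 2, 3), c(10, 11, 12)))
group_difference <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("group_difference needs at least two groups")
  }
  if (any(vapply(groups, length, 1L) == 0)) {
    abort("Every group must be non-empty")
  }
  if (length(groups) == 2) {
    ht <- suppressWarnings(
      wilcox.test(groups[[1]], groups[[2]], alternative = "two.sided")
    )
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "mann_whitney")
  } else {
    ht <- kruskal.test(groups)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "kruskal_wallis")
  }
}

#' Annual detection-frequency and median series with national usage
#'
#' Per-year survey summaries (sample count, detection frequency at the
#' threshold, conditional median) joined with national pesticide usage —
#' the sum over all provinces present in the usage table. Years with no
#' usage datum carry `NA` (recent usage statistics typically lag the
#' survey).
#'
#' @param records Survey tibble.
#' @param usage_table Optional usage tibble (see [read_usage()]).
#' @param threshold Detection threshold in mg/kg (default 0.01).
#' @return Tibble with columns `year`, `n`, `df_ge_threshold`,
#'   `median_above`, `usage_t`, ordered by year.
#' @export
annual_series <- function(records, usage_table = NULL, threshold = 0.01) {
  out <- summarize_residues(records, by = "year", threshold = threshold) |>
    dplyr::select("year", "n", "df_ge_threshold", "median_above")
  if (!is.null(usage_table)) {
    national <- usage_table |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(usage_t = sum(.data$pesticide_usage_t), .groups = "drop")
    out <- dplyr::left_join(out, national, by = "year")
  } else {
    out$usage_t <- NA_real_
  }
  dplyr::arrange(out, .data$year)
}

#' Province-level usage, dosage, and residue aggregates
#'
#' Builds the province-level quantities that spatial association analyses
#' pair: mean annual pesticide usage, mean pesticide dosage (usage over
#' production, years where both exist), and pooled detection frequency and
#' conditional median for a chosen record category.
#'
#' @param records Survey tibble.
#' @param usage_table Usage tibble (see [read_usage()]).
#' @param category Record category to pool residue metrics over (e.g.
#'   `"vegetable"` or `"fruit"`); `NULL` pools all records.
#' @param threshold Detection threshold in mg/kg.
#' @return Tibble with columns `province`, `mean_usage_t`,
#'   `mean_dosage_kg_t`, `n`, `df_ge_threshold`, `median_above`; provinces
#'   present in either input, `NA` where a side is missing.
#' @export
provincial_metrics <- function(records, usage_table, category = NULL,
                               threshold = 0.01) {
  if (!is.null(category)) {
    records <- records[records$category == category, , drop = FALSE]
  }
  residue <- summarize_residues(records, by = "province", threshold = threshold)
  usage <- usage_table |>
    dplyr::group_by(.data$province) |>
    dplyr::summarise(
      mean_usage_t = mean(.data$pesticide_usage_t, na.rm = TRUE),
      mean_dosage_kg_t = {
        ok <- !is.na(.data$production_t)
        if (any(ok)) {
          mean(pesticide_dosage(.data$pesticide_usage_t[ok], .data$production_t[ok]))
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    )
  dplyr::full_join(usage, residue, by = "province") |>
    dplyr::select("province", "mean_usage_t", "mean_dosage_kg_t",
                  "n", "df_ge_threshold", "median_above") |>
    dplyr::arrange(.data$province)
}
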