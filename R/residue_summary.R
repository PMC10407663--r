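#' Substitute censored concentrations at half the detection limit
#'
#' Non-detects are replaced by `lod / 2`, the standard convention for
#' left-censored residue data; detects are returned unchanged.
#'
#' @param records Survey tibble (see [read_survey()]).
#' @return Numeric vector of concentrations (mg/kg), one per record.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   food = "a", category = "vegetable", province = "SD", year = 2014L,
#'   source = "market", concentration = c(0.5, NA), censored = c(FALSE, TRUE),
#'   lod = 0.01, loq = 0.01
#' )
#' substitute_censored(recs) # 0.5, 0.005
substitute_censored <- function(records) {
  ifelse(records$censored, records$lod / 2, records$concentration)
}

#' Detection frequency at a threshold
#'
#' The fraction of records that are detects with concentration at or above
#' `threshold`. Censored records never count as detections, whatever their
#' LOD; a censored record whose LOD exceeds the threshold is flagged with a
#' validation warning because its detection status is genuinely ambiguous.
#'
#' @param records Survey tibble.
#' @param threshold Concentration threshold in mg/kg (default 0.01, the
#'   usual limit of quantification).
#' @return Fraction in `[0, 1]`.
#' @export
detection_frequency <- function(records, threshold = 0.01) {
  if (nrow(records) == 0) {
    abort("detection_frequency is undefined on an empty record set")
  }
  odd <- records$censored & records$lod > threshold
  if (any(odd)) {
    warn(sprintf(
      "%d censored record(s) have lod > threshold; they are counted as non-detects",
      sum(odd)
    ))
  }
  mean(!records$censored & records$concentration >= threshold)
}

#' Conditional median among samples at or above a threshold
#'
#' Median (midpoint rule for even counts) of detect concentrations at or
#' above `threshold`; `NA` when no sample qualifies.
#'
#' @inheritParams detection_frequency
#' @return Median in mg/kg, or `NA_real_`.
#' @export
conditional_median <- function(records, threshold = 0.01) {
  x <- records$concentration[!records$censored & records$concentration >= threshold]
  if (length(x) == 0) {
    return(NA_real_)
  }
  median(x)
}

#' Over-limit ratio against a maximum residue limit
#'
#' The fraction of records strictly exceeding the MRL (a sample exactly at
#' the limit is compliant). Censored records never exceed. Foods without a
#' limit return `NA`.
#'
#' @param records Survey tibble.
#' @param mrl A positive limit in mg/kg, or `NA` when the food has no
#'   limit, or a one-row tibble with an `mrl` column.
#' @return Fraction in `[0, 1]`, or `NA_real_` when no limit exists.
#' @export
over_limit_ratio <- function(records, mrl) {
  if (is.data.frame(mrl)) {
    mrl <- mrl$mrl[1]
  }
  if (is.na(mrl)) {
    return(NA_real_)
  }
  stopifnot(mrl > 0)
  if (nrow(records) == 0) {
    return(NA_real_)
  }
  mean(!records$censored & records$concentration > mrl)
}

#' Summarise a residue survey over grouping keys
#'
#' Computes, per group, the sample count, detection frequency at
#' `threshold`, the all-sample median (with non-detects substituted at half
#' LOD), the conditional median among samples at or above the threshold,
#' the maximum, and — when grouping by `food` and an MRL table is supplied
#' — the over-limit ratio.
#'
#' @param records Survey tibble.
#' @param by Character vector of grouping fields (any of `food`,
#'   `category`, `province`, `year`, `source`).
#' @param mrl_table Optional MRL tibble (see [read_mrl_table()]); used only
#'   when `"food"` is among the grouping fields.
#' @param threshold Detection threshold in mg/kg (default 0.01).
#' @param median_all_rule `"substituted"` (default) computes the all-sample
#'   median on half-LOD-substituted values; `"censored_as_nd"` reports `NA`
#'   whenever the central order statistic is a censored sample, mimicking
#'   tables that print "ND" for such medians.
#' @return Tibble with the grouping columns plus `n`, `df_ge_threshold`,
#'   `median_all`, `median_above`, `max_conc`, `olr`, ordered
#'   lexicographically by key.
#' @export
summarize_residues <- function(records, by = "food", mrl_table = NULL,
                               threshold = 0.01,
                               median_all_rule = c("substituted", "censored_as_nd")) {
  median_all_rule <- match.arg(median_all_rule)
  validate_survey(records)
  unknown <- setdiff(by, c("food", "category", "province", "year", "source"))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown grouping field(s): %s", paste(unknown, collapse = ", ")))
  }
  one_group <- function(g) {
    subst <- substitute_censored(g)
    med_all <- median(subst)
    if (median_all_rule == "censored_as_nd") {
      # median is "ND" when at least half the samples are censored
      if (mean(g$censored) >= 0.5) med_all <- NA_real_
    }
    tibble::tibble(
      n = nrow(g),
      df_ge_threshold = detection_frequency(g, threshold),
      median_all = med_all,
      median_above = conditional_median(g, threshold),
      max_conc = max(subst),
      olr = NA_real_
    )
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  if (!is.null(mrl_table) && "food" %in% by) {
    olr_by_food <- records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(function(g, key) {
        lim <- mrl_table$mrl[match(key$food, mrl_table$food)]
        tibble::tibble(olr = over_limit_ratio(g, if (length(lim) == 0) NA_real_ else lim))
      }) |>
      dplyr::ungroup()
    out$olr <- olr_by_food$olr[match(
      do.call(paste, c(out[by], sep = "\r")),
      do.call(paste, c(olr_by_food[by], sep = "\r"))
    )]
  }
  out
}

#' Format a fraction as a percentage string
#'
#' One decimal place, the convention residue monitoring tables use.
#'
#' @param x Numeric fraction(s).
#' @return Character vector like `"12.2%"`; `NA` maps to `"-"`.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.1f%%", 100 * x))
}
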