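#' Read a residue survey file
#'
#' A survey file is delimited text (comma or tab, auto-detected from the
#' header line) with one row per analysed sample and mandatory header
#' `food,category,province,year,source,concentration,censored,lod,loq`.
#' Non-detects are rows whose concentration field is the token `"ND"`
#' (case-insensitive), or an empty concentration together with a true
#' `censored` flag; they yield records with an absent (`NA`) concentration.
#' Concentrations are stored exactly as reported — the half-LOD substitution
#' for non-detects is a downstream summary operation
#' ([substitute_censored()]), never applied at parse time.
#'
#' @param path Path to the survey file.
#' @return A tibble of residue records with columns `food`, `category`
#'   (one of vegetable, fruit, mushroom, cereal, tea, potato), `province`,
#'   `year`, `source` (production/market/unknown), `concentration` (mg/kg,
#'   `NA` when censored), `censored` (logical), `lod`, `loq` (mg/kg).
#' @seealso [write_survey()], [generate_survey()]
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Survey file not found: %s", path))
  }
  df <- quiet_read(path, detect_delim(path))
  require_columns(
    df,
    c("food", "category", "province", "year", "source",
      "concentration", "censored", "lod", "loq"),
    "Survey file"
  )
  rows <- seq_len(nrow(df))

  conc_raw <- df$concentration
  nd <- !is.na(conc_raw) & toupper(trimws(conc_raw)) == "ND"
  censored_flag <- toupper(trimws(df$censored %||% "")) %in% c("TRUE", "T", "1", "YES")
  empty_conc <- is.na(conc_raw) | trimws(conc_raw) == ""
  censored <- nd | (empty_conc & censored_flag)

  conc_field <- ifelse(censored, NA_character_, conc_raw)
  concentration <- parse_strict_numeric(conc_field, "concentration", rows)

  records <- tibble::tibble(
    food = df$food,
    category = df$category,
    province = df$province,
    year = as.integer(parse_strict_numeric(df$year, "year", rows)),
    source = ifelse(is.na(df$source) | df$source == "", "unknown", df$source),
    concentration = concentration,
    censored = censored,
    lod = parse_strict_numeric(df$lod, "lod", rows),
    loq = parse_strict_numeric(df$loq, "loq", rows)
  )
  validate_survey(records)
}

#' Validate a tibble of residue records
#'
#' Checks the record invariants: censored records carry no concentration and
#' detects do; concentrations are non-negative; `lod <= loq` with both
#' positive; categories and sources are from the documented vocabularies.
#'
#' @param records A tibble as returned by [read_survey()].
#' @return `records`, invisibly unchanged, or an error naming the first
#'   offending row.
#' @export
validate_survey <- function(records) {
  require_columns(
    records,
    c("food", "category", "province", "year", "source",
      "concentration", "censored", "lod", "loq"),
    "Survey"
  )
  bad_cat <- !records$category %in% RECORD_CATEGORIES
  if (any(bad_cat)) {
    abort(sprintf(
      "Unknown category '%s' at row %d (expected one of %s)",
      records$category[which(bad_cat)[1]], which(bad_cat)[1],
      paste(RECORD_CATEGORIES, collapse = ", ")
    ))
  }
  bad_src <- !records$source %in% SOURCES
  if (any(bad_src)) {
    abort(sprintf("Unknown source '%s' at row %d",
                  records$source[which(bad_src)[1]], which(bad_src)[1]))
  }
  neg <- !is.na(records$concentration) & records$concentration < 0
  if (any(neg)) {
    abort(sprintf("Negative concentration at row %d", which(neg)[1]))
  }
  mismatch <- records$censored != is.na(records$concentration)
  if (any(mismatch)) {
    abort(sprintf(
      "Row %d violates the censoring invariant (censored records must have an absent concentration and detects a present one)",
      which(mismatch)[1]
    ))
  }
  bad_lod <- is.na(records$lod) | records$lod <= 0 |
    is.na(records$loq) | records$loq <= 0 | records$lod > records$loq
  if (any(bad_lod)) {
    abort(sprintf("Row %d needs 0 < lod <= loq", which(bad_lod)[1]))
  }
  invisible(records)
}

#' Write a residue survey file
#'
#' Emits the same dialect [read_survey()] reads: comma-delimited, censored
#' rows written with the `ND` token. Numeric fields are written with full
#' (round-trip exact) precision, so `read_survey(write_survey(x))`
#' reproduces `x` field for field and identical inputs give bit-identical
#' files.
#'
#' @param records Survey tibble (see [read_survey()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  validate_survey(records)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(
    food = records$food,
    category = records$category,
    province = records$province,
    year = as.integer(records$year),
    source = records$source,
    concentration = ifelse(records$censored, "ND", fmt(records$concentration)),
    censored = ifelse(records$censored, "TRUE", "FALSE"),
    lod = fmt(records$lod),
    loq = fmt(records$loq),
    stringsAsFactors = FALSE
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a maximum-residue-limit table
#'
#' Columns `food,mrl,authority`; a blank `mrl` means the food has no limit
#' (such foods are excluded from over-limit computation downstream).
#'
#' @param path Path to the MRL file (comma or tab delimited).
#' @return Tibble with columns `food`, `mrl` (mg/kg, `NA` when no limit),
#'   `authority` (`national_standard` or `ministry_guideline`, `NA` when no
#'   limit). Duplicate food names are an error (the limit would be
#'   ambiguous).
#' @export
read_mrl_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("MRL file not found: %s", path))
  }
  if (length(readLines(path, n = 1L)) == 0) {
    return(tibble::tibble(food = character(), mrl = numeric(), authority = character()))
  }
  df <- quiet_read(path, detect_delim(path))
  require_columns(df, c("food", "mrl"), "MRL file")
  if (nrow(df) == 0) {
    return(tibble::tibble(food = character(), mrl = numeric(), authority = character()))
  }
  dup <- duplicated(df$food)
  if (any(dup)) {
    abort(sprintf("Duplicate food '%s' in MRL table (ambiguous limit)", df$food[which(dup)[1]]))
  }
  mrl <- parse_strict_numeric(df$mrl, "mrl")
  if (any(!is.na(mrl) & mrl <= 0)) {
    abort("MRL values must be positive when present")
  }
  tibble::tibble(
    food = df$food,
    mrl = mrl,
    authority = if ("authority" %in% names(df)) {
      ifelse(is.na(mrl), NA_character_, df$authority)
    } else {
      ifelse(is.na(mrl), NA_character_, "national_standard")
    }
  )
}

#' Construct a population consumption profile
#'
#' @param population One of `children_2_7`, `adolescent_male`,
#'   `adolescent_female`, `adult_male`, `adult_female`.
#' @param intake_mean Named numeric vector of mean daily intakes (kg/day)
#'   for the four diet categories `vegetables`, `fruits`, `cereals`,
#'   `potatoes`.
#' @param body_weight_mean Mean body weight (kg).
#' @param cv Coefficient of variation applied to intake and body weight in
#'   Monte Carlo simulation (default 0.10).
#' @return An object of class `consumption_profile`.
#' @export
consumption_profile <- function(population, intake_mean, body_weight_mean, cv = 0.10) {
  population <- match.arg(population, POPULATIONS)
  missing_cat <- setdiff(DIET_CATEGORIES, names(intake_mean))
  if (length(missing_cat) > 0) {
    abort(sprintf("intake_mean is missing categories: %s", paste(missing_cat, collapse = ", ")))
  }
  intake_mean <- intake_mean[DIET_CATEGORIES]
  stopifnot(all(intake_mean > 0), body_weight_mean > 0, cv >= 0, cv < 1)
  structure(
    list(
      population = population,
      intake_mean = intake_mean,
      body_weight_mean = body_weight_mean,
      cv = cv
    ),
    class = "consumption_profile"
  )
}

#' @export
print.consumption_profile <- function(x, ...) {
  cat(sprintf("<consumption_profile: %s>\n", x$population))
  cat(sprintf("  body weight %.1f kg, cv %.2f\n", x$body_weight_mean, x$cv))
  for (cc in names(x$intake_mean)) {
    cat(sprintf("  %-10s %.3f kg/day\n", cc, x$intake_mean[[cc]]))
  }
  invisible(x)
}

#' Read consumption/body-weight profiles
#'
#' One row per population x category with columns
#' `population,category,intake_mean_kg_day,body_weight_kg,cv`; `cv` may be
#' omitted (defaults to 0.10). All five population groups must be present.
#'
#' @param path Path to the consumption file.
#' @return Named list of [consumption_profile()] objects, one per
#'   population.
#' @export
read_consumption <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Consumption file not found: %s", path))
  }
  df <- quiet_read(path, detect_delim(path))
  require_columns(df, c("population", "category", "intake_mean_kg_day", "body_weight_kg"),
                  "Consumption file")
  missing_pop <- setdiff(POPULATIONS, unique(df$population))
  if (length(missing_pop) > 0) {
    abort(sprintf("Consumption file is missing population(s): %s",
                  paste(missing_pop, collapse = ", ")))
  }
  intake <- parse_strict_numeric(df$intake_mean_kg_day, "intake_mean_kg_day")
  bw <- parse_strict_numeric(df$body_weight_kg, "body_weight_kg")
  cv <- if ("cv" %in% names(df)) parse_strict_numeric(df$cv, "cv") else rep(NA_real_, nrow(df))
  profiles <- lapply(POPULATIONS, function(pop) {
    idx <- which(df$population == pop)
    consumption_profile(
      population = pop,
      intake_mean = setNames(intake[idx], df$category[idx]),
      body_weight_mean = bw[idx][1],
      cv = if (all(is.na(cv[idx]))) 0.10 else cv[idx][!is.na(cv[idx])][1]
    )
  })
  setNames(profiles, POPULATIONS)
}

#' Read a provincial pesticide usage table
#'
#' Columns `province,year,pesticide_usage_t,production_t` (annual pesticide
#' usage and agricultural production in tons; production may be blank).
#'
#' @param path Path to the usage file.
#' @return Tibble with columns `province`, `year`, `pesticide_usage_t`,
#'   `production_t`.
#' @export
read_usage <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Usage file not found: %s", path))
  }
  df <- quiet_read(path, detect_delim(path))
  require_columns(df, c("province", "year", "pesticide_usage_t"), "Usage file")
  usage <- parse_strict_numeric(df$pesticide_usage_t, "pesticide_usage_t")
  production <- if ("production_t" %in% names(df)) {
    parse_strict_numeric(df$production_t, "production_t")
  } else {
    rep(NA_real_, nrow(df))
  }
  if (any(usage < 0, na.rm = TRUE)) abort("Pesticide usage must be non-negative")
  if (any(!is.na(production) & production <= 0)) abort("Production must be positive when present")
  tibble::tibble(
    province = df$province,
    year = as.integer(parse_strict_numeric(df$year, "year")),
    pesticide_usage_t = usage,
    production_t = production
  )
}
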