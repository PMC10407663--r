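#' Full chronic and acute risk table
#'
#' Runs [chronic_risk()] (combined diet) and [acute_risk()] (each of the
#' four diet categories) for every supplied population profile and returns
#' one tidy row per distribution.
#'
#' @param records Survey tibble covering the four diet categories.
#' @param profiles Named list of [consumption_profile()] objects (default
#'   [default_consumption()]).
#' @param config A [simulation_config()].
#' @return Tibble with columns `population`, `risk_type`, `category`,
#'   `median`, `p97.5`, `p99.9984`, `max`, `frac_gt_0.1`, `frac_gt_1`,
#'   `ar_upper`, and `contribution_*` columns for the chronic rows.
#' @export
risk_assessment <- function(records, profiles = default_consumption(),
                            config = simulation_config()) {
  cat_records <- split_diet_categories(records)
  rows <- list()
  for (profile in profiles) {
    cr <- chronic_risk(profile, cat_records, config)
    rows[[length(rows) + 1]] <- risk_row(cr)
    for (cc in DIET_CATEGORIES) {
      ar <- acute_risk(profile, cat_records[[cc]], cc, config)
      rows[[length(rows) + 1]] <- risk_row(ar)
    }
  }
  dplyr::bind_rows(rows)
}

risk_row <- function(d) {
  row <- tibble::tibble(
    population = d$population,
    risk_type = d$risk_type,
    category = d$category,
    median = d$percentiles[["p50"]],
    `p97.5` = d$percentiles[["p97.5"]],
    `p99.9984` = d$percentiles[["p99.9984"]],
    max = d$percentiles[["p100"]],
    `frac_gt_0.1` = d$exceedance[["0.1"]],
    frac_gt_1 = d$exceedance[["1"]],
    ar_upper = d$ar_upper %||% NA_real_
  )
  if (!is.null(d$contributions)) {
    for (cc in names(d$contributions)) {
      row[[paste0("contribution_", cc)]] <- d$contributions[[cc]]
    }
  }
  row
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the survey-to-risk pipeline
#'
#' Executes simulate (optional) -> summarize -> trend -> risk from a
#' structured YAML configuration and writes CSV artifacts plus a JSON run
#' manifest (command, seed, configuration digest, input digests,
#' timestamp). Identical inputs and seed give identical outputs apart from
#' the manifest timestamp. Any stage error aborts with the failing stage
#' named.
#'
#' Configuration keys (all optional except `seed`): `survey` (path to an
#' existing survey; when absent a survey is simulated from `specs`, the
#' packaged 66-food table by default), `mrl` (path; packaged table by
#' default), `consumption` (path; packaged profiles by default), `usage`
#' (path; trend runs without usage when absent), `summarize_by` (character
#' vector, default `"food"`), `threshold` (default 0.01), `n_iter`
#' (default 10,000), `cv`, `adi`, `arfd`.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir` or the current directory.
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config_path <- config
    config <- pipeline_stage("config", yaml::read_yaml(config))
  } else {
    config_path <- NULL
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  inputs <- character()

  # simulate (or load) ------------------------------------------------
  survey <- pipeline_stage("simulate", {
    if (!is.null(config$survey)) {
      inputs <- c(inputs, config$survey)
      read_survey(config$survey)
    } else {
      specs <- if (!is.null(config$specs)) {
        inputs <- c(inputs, config$specs)
        default_specs(config$specs)
      } else {
        default_specs()
      }
      generate_survey(specs, seed = seed)
    }
  })
  paths$survey <- file.path(out_dir, "survey.csv")
  write_survey(survey, paths$survey)

  # summarize ----------------------------------------------------------
  summary_tbl <- pipeline_stage("summarize", {
    mrl <- if (!is.null(config$mrl)) {
      inputs <- c(inputs, config$mrl)
      read_mrl_table(config$mrl)
    } else {
      default_mrl_table()
    }
    summarize_residues(
      survey,
      by = config$summarize_by %||% "food",
      mrl_table = mrl,
      threshold = config$threshold %||% 0.01
    )
  })
  paths$summary <- file.path(out_dir, "summary.csv")
  readr::write_csv(summary_tbl, paths$summary, progress = FALSE)

  # trend --------------------------------------------------------------
  trend_tbl <- pipeline_stage("trend", {
    usage <- if (!is.null(config$usage)) {
      inputs <- c(inputs, config$usage)
      read_usage(config$usage)
    } else {
      NULL
    }
    annual_series(survey, usage, threshold = config$threshold %||% 0.01)
  })
  paths$trend <- file.path(out_dir, "trend.csv")
  readr::write_csv(trend_tbl, paths$trend, progress = FALSE)

  # risk ---------------------------------------------------------------
  risk_tbl <- pipeline_stage("risk", {
    profiles <- if (!is.null(config$consumption)) {
      inputs <- c(inputs, config$consumption)
      read_consumption(config$consumption)
    } else {
      default_consumption(cv = config$cv %||% 0.10)
    }
    sim <- simulation_config(
      n_iter = config$n_iter %||% 10000,
      seed = seed,
      cv = config$cv %||% 0.10,
      adi = config$adi %||% 0.02,
      arfd = config$arfd %||% 0.02
    )
    risk_assessment(survey, profiles, sim)
  })
  paths$risk <- file.path(out_dir, "risk.csv")
  readr::write_csv(risk_tbl, paths$risk, progress = FALSE)

  # manifest -----------------------------------------------------------
  digest_files <- function(files) {
    files <- files[file.exists(files)]
    if (length(files) == 0) {
      return(stats::setNames(list(), character()))
    }
    as.list(tools::md5sum(files))
  }
  manifest <- list(
    command = "run_pipeline",
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_digest = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else {
      NA_character_
    },
    input_digests = digest_files(inputs),
    output_digests = digest_files(unlist(paths))
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
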