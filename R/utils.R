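#' Derive a reproducible child seed from a root seed and a label
#'
#' Simulation stages draw from independent streams keyed by a label (for
#' example `"adult_male/cereals/intake"`), so adding or removing one stream
#' never perturbs another's draws under the same root seed.
#'
#' @param seed Integer root seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "children_2_7/vegetables/conc")
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label), length(label) == 1)
  h <- 0
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483587
  }
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# Run code under a seed without disturbing the caller's RNG state; a NULL
# seed leaves the ambient stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

# readr without progress/column chatter
quiet_read <- function(path, delim) {
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
}

# Auto-detect comma vs tab from the header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    return(",")
  }
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# Parse a numeric field strictly: "" and NA stay NA, anything else must be a
# plain number (malformed fields are rejected, not coerced to NA).
parse_strict_numeric <- function(x, field, rows = seq_along(x)) {
  out <- rep(NA_real_, length(x))
  has <- !is.na(x) & x != ""
  suppressWarnings(out[has] <- as.numeric(x[has]))
  bad <- has & is.na(out)
  if (any(bad)) {
    abort(sprintf(
      "Malformed numeric value in column '%s' at row %s: '%s'",
      field, rows[which(bad)[1]], x[which(bad)[1]]
    ))
  }
  out
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
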