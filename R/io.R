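#' Read and validate a measurements table
#'
#' The measurements table is delimited text with a header and columns
#' `case_id`, `platform_id`, `score` (one row per tumor core per platform,
#' raw positive intensity in arbitrary units). Malformed or out-of-domain
#' rows are reported with their file line numbers.
#'
#' @param path Path to the delimited text file (delimiter auto-detected).
#' @return A validated tibble of intensity records.
#' @export
read_measurements <- function(path) {
  raw <- readr::read_delim(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  validate_measurements(raw, line_offset = 1L)
}

# shared validator so in-memory tables get the same contract as files;
# line_offset accounts for the header row when reporting line numbers
validate_measurements <- function(raw, line_offset = 0L) {
  need <- c("case_id", "platform_id", "score")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    mc_abort(sprintf("measurements table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad_parse <- which(is.na(score) & !is.na(raw$score))
  if (length(bad_parse) > 0L) {
    mc_abort(sprintf(
      "unparseable score on line(s): %s",
      paste(utils::head(bad_parse + line_offset, 5L), collapse = ", ")
    ))
  }
  bad_dom <- which(is.na(score) | score <= 0)
  if (length(bad_dom) > 0L) {
    mc_abort(sprintf(
      "nonpositive or missing score on line(s): %s",
      paste(utils::head(bad_dom + line_offset, 5L), collapse = ", ")
    ))
  }
  key <- paste(raw$case_id, raw$platform_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    mc_abort(sprintf(
      "duplicate (case_id, platform_id) pair(s): %s",
      paste(utils::head(unique(sub("\r", "/", key[dup])), 5L),
            collapse = ", ")
    ))
  }
  tibble(case_id = as.character(raw$case_id),
         platform_id = as.character(raw$platform_id),
         score = score)
}

#' Read and validate a clinical table
#'
#' Delimited text with header columns `case_id`, `time_months`, `event`,
#' plus optional categorical covariates and an optional `chromogen_percent`
#' column (pathologist percent-positive score, 0 for undetectable or an
#' integer between 1 and 95).
#'
#' @param path Path to the delimited text file.
#' @return A validated tibble of clinical records.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_delim(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  validate_clinical(raw)
}

validate_clinical <- function(raw) {
  need <- c("case_id", "time_months", "event")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    mc_abort(sprintf("clinical table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
  }
  out <- as_tibble(raw)
  out$case_id <- as.character(out$case_id)
  out$time_months <- suppressWarnings(as.numeric(out$time_months))
  ev <- suppressWarnings(as.numeric(out$event))
  if (any(is.na(out$time_months)) || any(out$time_months < 0)) {
    mc_abort("`time_months` must be nonnegative numbers.")
  }
  if (any(is.na(ev)) || !all(ev %in% c(0, 1))) {
    mc_abort("`event` must be 0 (censored) or 1 (recurrence).")
  }
  out$event <- as.integer(ev)
  if ("chromogen_percent" %in% names(out)) {
    cp <- suppressWarnings(as.numeric(out$chromogen_percent))
    ok <- !is.na(cp) & (cp == 0 | (cp >= 1 & cp <= 95)) & cp == round(cp)
    if (!all(ok)) {
      mc_abort(sprintf(
        "chromogen_percent outside {0} or [1, 95] for case(s): %s",
        paste(utils::head(out$case_id[!ok], 5L), collapse = ", ")
      ))
    }
    out$chromogen_percent <- as.integer(cp)
  }
  build_rfs(out)
}

#' Write the synthetic cohort tables as delimited text
#'
#' @param tables A list with `measurements` and `clinical` tibbles, as
#'   produced by [simulate_cohort_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    measurements = file.path(dir, "measurements.tsv"),
    clinical = file.path(dir, "clinical.tsv")
  )
  readr::write_tsv(tables$measurements, paths[["measurements"]])
  readr::write_tsv(tables$clinical, paths[["clinical"]])
  invisible(paths)
}
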