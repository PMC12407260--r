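#' Validate a cohort table
#'
#' A cohort is an ordinary tibble with one row per subject and, at minimum,
#' the canonical columns `age` (years at baseline), `time` (follow-up years)
#' and `event` (1 = death, 0 = right-censored), plus any number of numeric
#' biomarker columns. All modelling functions in bioclock take a cohort
#' data frame as their first argument.
#'
#' @param data A data frame with columns `age`, `time`, `event` and the
#'   biomarker columns named in `biomarkers`.
#' @param biomarkers Character vector of biomarker column names that will be
#'   used downstream (may be empty).
#' @return The input as a tibble, invisibly validated. Errors describe the
#'   first violated constraint.
#' @examples
#' cohort <- tibble::tibble(age = c(50, 60), time = c(5, 3),
#'                          event = c(0, 1), alb = c(44, 40))
#' validate_cohort(cohort, "alb")
#' @export
validate_cohort <- function(data, biomarkers = character()) {
  data <- tibble::as_tibble(data)
  needed <- c("age", "time", "event", biomarkers)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(names(data), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(biomarkers)) {
    stop("duplicated biomarker names: ",
         paste(unique(biomarkers[duplicated(biomarkers)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) & !is.na(v))
      stop("column '", col, "' is not numeric",
           if (length(bad) > 0) paste0(" (first offending row: ", bad[1], ")"),
           call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("column '", col, "' contains missing or non-finite values; ",
           "drop incomplete rows first (see read_cohort())", call. = FALSE)
    }
  }
  if (any(data$time < 0)) stop("follow-up time must be >= 0", call. = FALSE)
  if (!all(data$event %in% c(0, 1))) {
    stop("event must be coded 0 (censored) / 1 (death); found: ",
         paste(head(setdiff(unique(data$event), c(0, 1)), 3), collapse = ", "),
         call. = FALSE)
  }
  data
}

#' Read a cohort from delimited text
#'
#' Reads a delimited file with a header row, renames the mapped columns to
#' the canonical names (`age`, `time`, `event`, optionally `sex` and an id
#' column), coerces biomarkers to numeric, and drops rows with missing
#' values in any mapped column (complete-case analysis). The number of
#' dropped rows is reported with a message.
#'
#' @param path Path to a CSV/TSV file (delimiter guessed by extension;
#'   override with `delim`).
#' @param column_map Named character vector mapping canonical names to file
#'   columns, e.g. `c(age = "AGE_YRS", time = "fu_years", event = "died")`.
#'   Must contain `age`, `time`, `event`; may contain `sex` and `id`.
#' @param biomarkers Character vector of biomarker column names as they
#'   appear in the file (kept under the same names).
#' @param delim Field delimiter; default `","` unless the path ends in
#'   `.tsv`/`.txt`, then tab.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, column_map = c(age = "age", time = "time", event = "event"),
                        biomarkers = character(), delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (canon in c("age", "time", "event")) {
    if (!canon %in% names(column_map)) {
      stop("column_map must name a '", canon, "' column", call. = FALSE)
    }
  }
  wanted <- c(unname(column_map), biomarkers)
  missing <- setdiff(wanted, names(raw))
  if (length(missing) > 0) {
    stop("file lacks mapped column(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(names(raw), collapse = ", "), call. = FALSE)
  }
  out <- raw[, wanted, drop = FALSE]
  names(out)[match(unname(column_map), names(out))] <- names(column_map)
  for (col in c("age", "time", "event", biomarkers)) {
    if (!is.numeric(out[[col]])) {
      out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
    }
  }
  keep <- complete.cases(out[, c("age", "time", "event", biomarkers)])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("read_cohort: dropped ", n_drop, " of ", nrow(out),
            " rows with missing values in mapped columns")
  }
  validate_cohort(out[keep, , drop = FALSE], biomarkers)
}

#' Write a cohort (and optional generating truth) to disk
#'
#' Writes the cohort as plain CSV. When the cohort carries a generating
#' Gompertz truth (as produced by [simulate_cohort()]), or one is supplied,
#' it is written as a sidecar JSON file so simulations are self-describing.
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @param truth Optional [gompertz_ph] model; defaults to the cohort's
#'   `truth` attribute when present.
#' @param truth_path Sidecar JSON path; default replaces the extension of
#'   `path` with `_truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, truth = attr(data, "truth"),
                         truth_path = NULL) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  if (!is.null(truth)) {
    if (is.null(truth_path)) {
      truth_path <- sub("\\.[A-Za-z]+$", "", path)
      truth_path <- paste0(truth_path, "_truth.json")
    }
    write_model(truth, truth_path)
  }
  invisible(path)
}
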