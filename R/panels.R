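#' Decompose the biological-age gap into biomarker panels
#'
#' Splits a clock's age gap into named panel contributions — e.g.
#' cardiometabolic, inflammatory, neurological and oncological subsets of
#' a proteomic clock. For panel \eqn{p} the per-subject panel gap is
#' \deqn{\mathrm{Diff}_p = \sum_{i \in p} c_i (x_i - \bar x_i)}
#' with \eqn{\bar x_i} the cohort mean, so every panel gap has cohort
#' mean zero, and the panel gaps (plus an `unassigned` column when the
#' panels do not cover all clock biomarkers) sum to the total gap up to
#' its subject-invariant constant shift.
#'
#' @param data Cohort with the clock's biomarker columns.
#' @param clock A [bioage_clock].
#' @param panels Named list of character vectors partitioning (a subset
#'   of) the clock's biomarkers; no biomarker may appear in two panels.
#' @return A tibble with one column per panel (plus `unassigned` if
#'   needed), one row per subject.
#' @export
decompose_diff <- function(data, clock, panels) {
  if (length(panels) < 1 || is.null(names(panels)) || any(names(panels) == "")) {
    stop("panels must be a non-empty named list", call. = FALSE)
  }
  all_members <- unlist(panels, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("biomarker(s) assigned to more than one panel: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(all_members, names(clock$coefficients))
  if (length(unknown) > 0) {
    stop("panel member(s) not in the clock: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  miss <- setdiff(names(clock$coefficients), names(data))
  if (length(miss) > 0) {
    stop("data lacks clock biomarker column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unassigned <- setdiff(names(clock$coefficients), all_members)
  if (length(unassigned) > 0) panels <- c(panels, list(unassigned = unassigned))
  panel_col <- function(members) {
    X <- as.matrix(data[, members, drop = FALSE])
    Xc <- sweep(X, 2, colMeans(X))
    drop(Xc %*% clock$coefficients[members])
  }
  tibble::as_tibble(purrr::map(panels, panel_col))
}

#' Count-based multi-panel risk score
#'
#' Counts, for each subject, the number of panels in which their panel
#' age gap lies in the top `quantile` of the cohort (at or above the
#' empirical `1 - quantile` quantile; values tied with the threshold
#' count as high risk, making the score deterministic). With four panels
#' and the default top 25% this is the 0-4 risk score used to flag
#' subjects ageing fast on several biological axes at once.
#'
#' @param panel_diffs Tibble of per-subject panel gaps, as returned by
#'   [decompose_diff()].
#' @param quantile High-risk tail fraction in (0, 1); default 0.25.
#' @param panels Columns to score; defaults to all numeric columns.
#' @return `panel_diffs` with an integer `risk_score` column appended.
#' @export
risk_score <- function(panel_diffs, quantile = 0.25, panels = NULL) {
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1) {
    stop("quantile must be a single value in (0, 1)", call. = FALSE)
  }
  panel_diffs <- tibble::as_tibble(panel_diffs)
  if (is.null(panels)) {
    panels <- names(panel_diffs)[vapply(panel_diffs, is.numeric, logical(1))]
  }
  if (length(panels) < 1) stop("need at least one panel column", call. = FALSE)
  high <- vapply(panels, function(nm) {
    thr <- stats::quantile(panel_diffs[[nm]], probs = 1 - quantile,
                           names = FALSE, type = 7)
    as.integer(panel_diffs[[nm]] >= thr)
  }, integer(nrow(panel_diffs)))
  panel_diffs$risk_score <- as.integer(rowSums(matrix(high, nrow = nrow(panel_diffs))))
  panel_diffs
}
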