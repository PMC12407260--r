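#' Harrell's concordance index
#'
#' Probability that, of a randomly chosen comparable pair, the subject
#' with the higher risk score dies first. A pair is comparable when the
#' earlier observed time belongs to a subject who died (strictly earlier;
#' tied times are never comparable); score ties count 0.5. Rank-based, so
#' invariant to strictly increasing transforms of the score.
#'
#' @param score Per-subject risk score (higher = higher risk).
#' @param time Follow-up time in years.
#' @param event Death indicator (1 death, 0 censored).
#' @return Concordance fraction in \[0, 1\].
#' @examples
#' c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))  # perfect ranking -> 1
#' @export
c_index <- function(score, time, event) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(score) || anyNA(time) || anyNA(event)) stop("NA in inputs", call. = FALSE)
  conc <- 0
  comp <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0) next
    comp <- comp + m
    conc <- conc + sum(score[i] > score[later]) + 0.5 * sum(score[i] == score[later])
  }
  if (comp == 0) stop("no comparable pairs", call. = FALSE)
  conc / comp
}

#' Fixed-horizon mortality AUC via logistic regression
#'
#' Binary-classification accuracy of a score for death within `horizon`
#' years. Deaths are subjects with an event at or before the horizon;
#' survivors are subjects still under observation at the horizon;
#' subjects censored before the horizon are excluded (simple-exclusion
#' convention). A single-variable logistic model is fitted and the AUC of
#' its fitted probabilities reported alongside the rank (Mann-Whitney)
#' AUC of the raw score — the two agree whenever the fitted slope is
#' positive, since the logistic map is then monotone.
#'
#' @inheritParams c_index
#' @param horizon Horizon in years (default 10).
#' @return A one-row tibble: `auc_logistic`, `auc_rank`, `n_deaths`,
#'   `n_survivors`, `n_excluded`, `horizon`.
#' @export
horizon_auc <- function(score, time, event, horizon = 10) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  death <- event == 1 & time <= horizon
  survivor <- !death & time >= horizon
  usable <- death | survivor
  if (sum(death) == 0 || sum(survivor) == 0) {
    stop("degenerate outcome at horizon ", horizon,
         ": need at least one death and one survivor", call. = FALSE)
  }
  y <- as.integer(death[usable])
  s <- score[usable]
  fit <- glm(y ~ s, family = binomial())
  tibble::tibble(
    auc_logistic = rank_auc(fitted(fit), y),
    auc_rank = rank_auc(s, y),
    n_deaths = sum(y == 1),
    n_survivors = sum(y == 0),
    n_excluded = sum(!usable),
    horizon = horizon
  )
}

# Mann-Whitney AUC: P(score_case > score_control) + 0.5 P(tie)
rank_auc <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kaplan-Meier curves for extreme age-gap quantile groups
#'
#' Splits subjects into the top and bottom `quantile` of an age-gap (or
#' any risk) variable — the fast- and slow-ageing tails — optionally
#' within age strata, and returns Kaplan-Meier product-limit survival
#' curves with Greenwood log-log confidence intervals for each group.
#'
#' @param data Cohort with `time` and `event` columns.
#' @param diff Column name (string) of the risk variable; default
#'   `"bioage_diff"`.
#' @param quantile Tail fraction in (0, 0.5\]; default 0.25.
#' @param age_breaks Optional numeric breaks for age stratification
#'   (e.g. `c(45, 55, 65, 75, 85)`, the conventional 45-54 / 55-64 /
#'   65-74 / 75-85 decades); quantiles are then computed within each
#'   stratum. `NULL` (default) uses the whole cohort.
#' @return A tibble of curves: `stratum`, `group` (`"high"`/`"low"`),
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`. Curves start
#'   at 1 and are non-increasing.
#' @export
km_quantile_groups <- function(data, diff = "bioage_diff", quantile = 0.25,
                               age_breaks = NULL) {
  if (quantile <= 0 || quantile > 0.5) stop("quantile must be in (0, 0.5]", call. = FALSE)
  data <- validate_cohort(tibble::as_tibble(data), character())
  if (!diff %in% names(data)) stop("no column '", diff, "' in data", call. = FALSE)
  strata <- if (is.null(age_breaks)) {
    list(all = data)
  } else {
    labs <- paste(head(age_breaks, -1), age_breaks[-1], sep = "-")
    grp <- cut(data$age, breaks = age_breaks, labels = labs,
               include.lowest = TRUE, right = FALSE)
    split(data[!is.na(grp), , drop = FALSE], grp[!is.na(grp)])
  }
  purrr::map_dfr(names(strata), function(snm) {
    d <- strata[[snm]]
    x <- d[[diff]]
    hi <- d[x >= stats::quantile(x, 1 - quantile, names = FALSE), , drop = FALSE]
    lo <- d[x <= stats::quantile(x, quantile, names = FALSE), , drop = FALSE]
    if (nrow(hi) == 0 || nrow(lo) == 0) {
      stop("empty quantile group in stratum ", snm, call. = FALSE)
    }
    purrr::map_dfr(list(high = hi, low = lo), function(g) {
      sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = g,
                              conf.type = "log-log")
      tibble::tibble(time = c(0, sf$time), n_risk = c(nrow(g), sf$n.risk),
                     n_event = c(0, sf$n.event), surv = c(1, sf$surv),
                     lower = c(1, sf$lower), upper = c(1, sf$upper))
    }, .id = "group") |>
      dplyr::mutate(stratum = snm, .before = 1)
  })
}

#' Cox hazard ratio per one-year increase of the age gap
#'
#' Fits a Cox proportional-hazards model (Breslow ties) of mortality on
#' the age-gap variable, adjusted for chronological age and, when
#' present, sex, and reports the hazard ratio per +1 year of the gap
#' with a Wald 95% confidence interval.
#'
#' @inheritParams km_quantile_groups
#' @param adjust Adjustment columns; defaults to `age` plus `sex` when
#'   the data has one. Use `character()` for a crude model.
#' @return A one-row tibble: `term`, `hr`, `conf_low`, `conf_high`,
#'   `p_value`, `n`, `n_events`.
#' @export
cox_hr_per_year <- function(data, diff = "bioage_diff",
                            adjust = intersect(c("age", "sex"), names(data))) {
  data <- validate_cohort(tibble::as_tibble(data), character())
  if (!diff %in% names(data)) stop("no column '", diff, "' in data", call. = FALSE)
  rhs <- paste(c(sprintf("`%s`", diff), sprintf("`%s`", adjust)), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = data, ties = "breslow")
  if (!is.null(fit$info) || any(is.na(coef(fit)))) {
    warning("Cox fit reported convergence diagnostics; interpret with care",
            call. = FALSE)
  }
  b <- coef(fit)[1]
  se <- sqrt(diag(fit$var))[1]
  z <- b / se
  tibble::tibble(
    term = diff,
    hr = exp(b),
    conf_low = exp(b - 1.96 * se),
    conf_high = exp(b + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n = fit$n,
    n_events = fit$nevent
  )
}

#' PCA age: first principal components regressed on age
#'
#' Benchmark comparator for linear clocks: biomarkers are standardized,
#' the first `n_components` principal-component scores are regressed on
#' chronological age by least squares, and the fitted value is returned
#' as the subject's PCA age.
#'
#' @param data Cohort with `age` and the biomarker columns.
#' @param biomarkers Biomarker columns to use.
#' @param n_components Number of leading components (default 5); capped
#'   at the number of biomarkers with a warning.
#' @return The input tibble with a `pca_age` column appended.
#' @export
pca_age <- function(data, biomarkers, n_components = 5) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(c("age", biomarkers), names(data))
  if (length(missing) > 0) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (n_components > length(biomarkers)) {
    warning("n_components exceeds the number of biomarkers; using all ",
            length(biomarkers), call. = FALSE)
    n_components <- length(biomarkers)
  }
  pc <- prcomp(as.matrix(data[, biomarkers, drop = FALSE]),
               center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  fit <- lm(data$age ~ scores)
  dplyr::mutate(data, pca_age = unname(fitted(fit)))
}

#' Mahalanobis distance statistic from a reference state
#'
#' Benchmark comparator: the per-subject Mahalanobis distance
#' \eqn{\sqrt{(x-\mu)^\top \Sigma^{-1} (x-\mu)}} of the biomarker vector
#' from a reference mean and covariance (default: the cohort itself; a
#' young-adult reference subsample can be passed explicitly). A singular
#' covariance is ridge-regularized with a warning.
#'
#' @inheritParams pca_age
#' @param center Reference mean vector (default cohort means).
#' @param covariance Reference covariance matrix (default cohort
#'   covariance).
#' @return The input tibble with an `mds` column appended.
#' @export
mahalanobis_mds <- function(data, biomarkers, center = NULL,
                            covariance = NULL) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(biomarkers, names(data))
  if (length(missing) > 0) {
    stop("data lacks biomarker column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[, biomarkers, drop = FALSE])
  if (is.null(center)) center <- colMeans(X)
  if (is.null(covariance)) covariance <- stats::cov(X)
  if (inherits(try(solve(covariance), silent = TRUE), "try-error") ||
      rcond(covariance) < 1e-12) {
    warning("reference covariance is (near-)singular; ",
            "applying a ridge of 1e-8 * mean diagonal", call. = FALSE)
    covariance <- covariance + diag(1e-8 * mean(diag(covariance)),
                                    ncol(covariance))
  }
  dplyr::mutate(data, mds = sqrt(mahalanobis(X, center, covariance)))
}

#' Benchmark one or more clocks on a cohort
#'
#' Runs the standard evaluation battery for each clock: Harrell's
#' C-index of the predicted biological age, fixed-horizon mortality AUC,
#' the Cox hazard ratio per +1 year of the age gap (age/sex adjusted),
#' and Kaplan-Meier curves for the top and bottom age-gap quartiles.
#'
#' @param data Cohort tibble with `age`, `time`, `event` and every
#'   clock's biomarker columns.
#' @param clocks Named list of [bioage_clock] objects.
#' @param horizon AUC horizon in years (default 10).
#' @param quantile KM tail fraction (default 0.25).
#' @return An `evaluation_report`: list with `metrics` (one row per
#'   clock) and `km` (named list of curve tibbles).
#' @export
evaluate_clocks <- function(data, clocks, horizon = 10, quantile = 0.25) {
  if (is.null(names(clocks)) || any(names(clocks) == "")) {
    stop("clocks must be a named list", call. = FALSE)
  }
  data <- validate_cohort(tibble::as_tibble(data), character())
  km <- list()
  metrics <- purrr::map_dfr(names(clocks), function(nm) {
    pred <- predict_bioage(data, clocks[[nm]])
    horizon_out <- horizon_auc(pred$bioage, pred$time, pred$event, horizon)
    hr <- cox_hr_per_year(pred, diff = "bioage_diff")
    km[[nm]] <<- km_quantile_groups(pred, "bioage_diff", quantile)
    tibble::tibble(
      clock = nm,
      c_index = c_index(pred$bioage, pred$time, pred$event),
      auc = horizon_out$auc_logistic,
      auc_rank = horizon_out$auc_rank,
      hr_per_year = hr$hr,
      hr_conf_low = hr$conf_low,
      hr_conf_high = hr$conf_high,
      n = nrow(pred),
      n_events = sum(pred$event)
    )
  })
  structure(list(metrics = metrics, km = km, horizon = horizon,
                 quantile = quantile),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Clock evaluation report (AUC horizon ", x$horizon, " y, KM tails ",
      x$quantile * 100, "%)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_clocks
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics
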