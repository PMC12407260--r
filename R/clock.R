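#' Construct a linear biological-age clock
#'
#' A biological-age clock is the linear map
#' \deqn{\mathrm{BioAge} = CA + \sum_i c_i \, x_i + c_0}
#' with per-biomarker coefficients \eqn{c_i} in years per biomarker unit
#' and a constant \eqn{c_0} in years. Clocks are usually produced by
#' [derive_clock()] from two fitted Gompertz models (the coefficients are
#' then the ratios \eqn{\beta_{2i}/\beta_1}), but can also be built
#' directly from published coefficients, as [light_clock()] does.
#'
#' @param coefficients Named numeric vector, years per biomarker unit.
#' @param constant Clock constant in years.
#' @param beta1 The age log-hazard coefficient used as denominator when the
#'   clock was derived (NA for published clocks that do not report it).
#' @param reference_values Optional named numeric vector of biomarker
#'   reference levels used to report per-biomarker contributions to the
#'   age gap; defaults to training-cohort means in [derive_clock()].
#' @param provenance Free-text origin tag (e.g. `"derived"`, `"light"`).
#' @return An object of class `bioage_clock`.
#' @export
bioage_clock <- function(coefficients, constant, beta1 = NA_real_,
                         reference_values = NULL, provenance = "manual") {
  coefficients <- unlist(coefficients)
  if (length(coefficients) == 0 || is.null(names(coefficients)) ||
      any(names(coefficients) == "")) {
    stop("coefficients must be a non-empty named vector", call. = FALSE)
  }
  if (!is.finite(constant)) stop("clock constant must be finite", call. = FALSE)
  if (!is.null(reference_values)) {
    reference_values <- unlist(reference_values)
    extra <- setdiff(names(reference_values), names(coefficients))
    if (length(extra) > 0) {
      stop("reference values for unknown biomarker(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(coefficients = coefficients, constant = constant, beta1 = beta1,
         reference_values = reference_values, provenance = provenance),
    class = "bioage_clock"
  )
}

#' Derive a biological-age clock from two Gompertz PH models
#'
#' Converts a pair of Gompertz mortality models — model 1 with
#' chronological age only (hazard \eqn{h_1}), model 2 with age plus
#' biomarkers (hazard \eqn{h_2}) — into a linear clock. Biological age is
#' the age at which model 1's hazard matches the subject's model-2 hazard
#' at baseline (t = 0):
#' \deqn{\mathrm{BioAge} = CA + \sum_i \frac{\beta_{2i}}{\beta_1} x_i +
#'   \frac{1}{\beta_1}\log\left(\gamma \frac{rate_2}{rate_1}\right).}
#' The bias-correction factor \eqn{\gamma} equates the two models'
#' empirical baseline hazards over the training cohort. The default
#' estimator takes the constant as the cohort mean of
#' \eqn{(1/\beta_1)\log(h_{1j}/h_{2j} \cdot rate_2/rate_1)} (mean of
#' logs); `gamma = "ratio_of_means"` instead uses the scalar
#' \eqn{\gamma = \bar h_1 / \bar h_2}. Under the shared-age-coefficient
#' fit (model 2 with `fix_beta_age` at model 1's \eqn{\beta_1}) the
#' mean-of-logs constant reduces analytically to
#' \eqn{-(1/\beta_1)\sum_i \beta_{2i} \bar x_i}, which makes the
#' training-cohort mean of BioAgeDiff exactly zero.
#'
#' @param data The training cohort both models were fitted on.
#' @param model1 Age-only [gompertz_ph] model.
#' @param model2 Age + biomarkers [gompertz_ph] model (>= 1 biomarker).
#' @param gamma `"mean_log"` (default) or `"ratio_of_means"`.
#' @return A [bioage_clock] with `reference_values` set to the
#'   training-cohort biomarker means and `provenance = "derived"`.
#' @examples
#' truth <- gompertz_ph(2e-5, 0.09, 0.09, c(crp = 0.3))
#' cohort <- simulate_cohort(2000, truth,
#'                           list(crp = bm_normal(1, 1)), seed = 7)
#' m1 <- fit_gompertz(cohort)
#' m2 <- fit_gompertz(cohort, "crp", fix_beta_age = m1$beta_age)
#' derive_clock(cohort, m1, m2)
#' @export
derive_clock <- function(data, model1, model2,
                         gamma = c("mean_log", "ratio_of_means")) {
  gamma <- match.arg(gamma)
  stopifnot(inherits(model1, "gompertz_ph"), inherits(model2, "gompertz_ph"))
  if (length(model1$biomarkers) != 0) {
    stop("model1 must be the age-only model (no biomarkers)", call. = FALSE)
  }
  if (length(model2$biomarkers) == 0) {
    stop("model2 must include at least one biomarker", call. = FALSE)
  }
  beta1 <- model1$beta_age
  if (!is.finite(beta1) || beta1 <= 0) {
    stop("model1 age coefficient must be > 0: the clock is undefined when ",
         "mortality hazard does not increase with age", call. = FALSE)
  }
  data <- validate_cohort(data, model2$biomarkers)

  # per-subject baseline (t = 0) hazards of the two models
  log_h1 <- log(model1$rate) + gompertz_lp(model1, data)
  log_h2 <- log(model2$rate) + gompertz_lp(model2, data)
  log_rate_ratio <- log(model2$rate) - log(model1$rate)
  constant <- switch(
    gamma,
    mean_log = mean((log_h1 - log_h2 + log_rate_ratio) / beta1),
    ratio_of_means = (log(mean(exp(log_h1)) / mean(exp(log_h2))) +
                        log_rate_ratio) / beta1
  )

  bioage_clock(
    coefficients = model2$beta / beta1,
    constant = constant,
    beta1 = beta1,
    reference_values = colMeans(data[, model2$biomarkers, drop = FALSE]),
    provenance = "derived"
  )
}

#' Derive a clock from Cox proportional-hazards fits
#'
#' Semiparametric counterpart of [derive_clock()] used as a cross-check:
#' the age coefficient comes from a Cox model with age alone, the
#' biomarker coefficients from a Cox model with the age term held at that
#' value via an offset (the shared-age-coefficient protocol). Because the
#' Cox baseline hazard is unspecified there is no rate ratio; the constant
#' is chosen so the training-cohort mean age gap is zero, matching the
#' Gompertz clock's centering.
#'
#' @inheritParams derive_clock
#' @param biomarkers Biomarker columns to include.
#' @return A [bioage_clock] with `provenance = "cox"`.
#' @export
derive_clock_cox <- function(data, biomarkers) {
  data <- validate_cohort(data, biomarkers)
  s <- survival::Surv(data$time, data$event)
  fit1 <- survival::coxph(s ~ age, data = data, ties = "breslow")
  beta1 <- unname(coef(fit1)["age"])
  if (beta1 <= 0) stop("Cox age coefficient must be > 0", call. = FALSE)
  X <- as.matrix(data[, biomarkers, drop = FALSE])
  off <- beta1 * data$age
  fit2 <- survival::coxph(s ~ X + offset(off), ties = "breslow")
  beta2 <- setNames(unname(coef(fit2)), biomarkers)
  coefs <- beta2 / beta1
  bioage_clock(
    coefficients = coefs,
    constant = -sum(coefs * colMeans(X)),
    beta1 = beta1,
    reference_values = colMeans(X),
    provenance = "cox"
  )
}

# coefficient part sum_i c_i x_i for each row; errors name missing columns
clock_linear_part <- function(clock, data) {
  missing <- setdiff(names(clock$coefficients), names(data))
  if (length(missing) > 0) {
    stop("data lacks clock biomarker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, names(clock$coefficients), drop = FALSE])
  drop(X %*% clock$coefficients)
}

#' Predict biological age and the age gap
#'
#' `predict_bioage()` appends `bioage` (and `bioage_diff = bioage - age`)
#' to a cohort: \eqn{\mathrm{BioAge} = CA + \sum_i c_i x_i + c_0}. A
#' positive gap means the subject is biologically older than their
#' calendar age. `bioage_diff()` additionally reports, when the clock
#' carries reference values, each biomarker's contribution
#' \eqn{c_i (x_i - x_i^{ref})} to the gap (columns `contrib_<name>`) and
#' the residual constant `diff_constant`; contributions plus the residual
#' constant sum to the gap exactly.
#'
#' @param data Data frame with `age` and the clock's biomarker columns.
#' @param clock A [bioage_clock].
#' @return The input tibble with prediction columns appended.
#' @export
predict_bioage <- function(data, clock) {
  data <- tibble::as_tibble(data)
  if (!"age" %in% names(data)) stop("data must contain an 'age' column", call. = FALSE)
  lin <- clock_linear_part(clock, data)
  dplyr::mutate(data,
                bioage = .data$age + lin + clock$constant,
                bioage_diff = lin + clock$constant)
}

#' @rdname predict_bioage
#' @export
bioage_diff <- function(data, clock) {
  out <- predict_bioage(data, clock)
  if (!is.null(clock$reference_values)) {
    refs <- clock$reference_values
    for (nm in names(clock$coefficients)) {
      ref <- if (nm %in% names(refs)) refs[[nm]] else 0
      out[[paste0("contrib_", nm)]] <-
        clock$coefficients[[nm]] * (out[[nm]] - ref)
    }
    have <- intersect(names(clock$coefficients), names(refs))
    out$diff_constant <- clock$constant +
      sum(clock$coefficients[have] * refs[have])
  }
  out
}

#' The published three-biomarker "light" clock
#'
#' `light_clock()` loads the packaged light biological-age clock — a
#' three-biomarker clock with published coefficients:
#' \deqn{\mathrm{BioAge} = Age + 8.3313\,\mathrm{Creatinine} +
#'   0.8270\,\mathrm{Glucose} + 5.7305\,\log(\mathrm{CRP}) - 13.5298.}
#' The log is natural. The source publication does not state the biomarker
#' units; no unit conversion is applied, so inputs must be on the scale
#' the coefficients were estimated on (conventionally creatinine in mg/dL,
#' glucose in mmol/L, CRP in mg/L).
#'
#' `light_bioage()` evaluates it on a cohort with columns `age`,
#' `creatinine`, `glucose` and `crp` (raw CRP; the log transform is
#' applied internally).
#'
#' @param data Data frame with `age`, `creatinine`, `glucose`, `crp`.
#' @return `light_clock()`: a [bioage_clock]. `light_bioage()`: the input
#'   with `log_crp`, `bioage` and `bioage_diff` columns appended.
#' @examples
#' light_bioage(tibble::tibble(age = 60, creatinine = 0.9,
#'                             glucose = 5.5, crp = 1))
#' @export
light_clock <- function() {
  read_clock(system.file("extdata", "light_clock.json", package = "bioclock",
                         mustWork = TRUE))
}

#' @rdname light_clock
#' @export
light_bioage <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("age", "creatinine", "glucose", "crp")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(data$crp <= 0)) {
    stop("crp must be > 0 (log-transformed by the clock)", call. = FALSE)
  }
  if (any(data$creatinine < 0) || any(data$glucose < 0)) {
    warning("negative creatinine or glucose values are clinically implausible",
            call. = FALSE)
  }
  data$log_crp <- log(data$crp)
  predict_bioage(data, light_clock())
}

#' @export
print.bioage_clock <- function(x, ...) {
  cat("Biological-age clock (", x$provenance, ")\n", sep = "")
  cat("  BioAge = age")
  for (nm in names(x$coefficients)) {
    cat(sprintf(" %+.4f*%s", x$coefficients[[nm]], nm))
  }
  cat(sprintf(" %+.4f\n", x$constant))
  if (is.finite(x$beta1)) cat(sprintf("  beta1 (age log-hazard) = %.5f /yr\n", x$beta1))
  invisible(x)
}

#' Tidy a biological-age clock
#'
#' @param x A [bioage_clock].
#' @param ... Unused.
#' @return One row per term (biomarkers and the constant) with `term`,
#'   `estimate` (years per unit), and `reference` where available.
#' @export
tidy.bioage_clock <- function(x, ...) {
  refs <- x$reference_values
  tibble::tibble(
    term = c(names(x$coefficients), "(constant)"),
    estimate = c(unname(x$coefficients), x$constant),
    reference = c(
      vapply(names(x$coefficients),
             function(nm) if (!is.null(refs) && nm %in% names(refs)) refs[[nm]] else NA_real_,
             numeric(1)),
      NA_real_)
  )
}

#' @rdname tidy.bioage_clock
#' @export
glance.bioage_clock <- function(x, ...) {
  tibble::tibble(n_biomarkers = length(x$coefficients),
                 constant = x$constant, beta1 = x$beta1,
                 provenance = x$provenance)
}
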