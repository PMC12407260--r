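#' Construct a Gompertz proportional-hazards model
#'
#' The mortality hazard at `t` years after baseline for a subject with
#' chronological age `CA` and biomarker vector `x` is
#' \deqn{h(t) = \mathrm{rate} \cdot \exp(\beta_{age} CA + \sum_i \beta_i x_i
#'   + \mathrm{shape} \cdot t).}
#' `rate` is the baseline hazard scale (per year, > 0), `shape` the Gompertz
#' time coefficient (per year; negative values are permitted and give a
#' defective, decelerating hazard), `beta_age` the log-hazard slope per year
#' of age, and `beta` the named biomarker coefficients on their native
#' scales.
#'
#' @param rate Baseline hazard scale, > 0.
#' @param shape Gompertz time coefficient per year.
#' @param beta_age Coefficient of chronological age.
#' @param beta Named numeric vector of biomarker coefficients (may be
#'   empty).
#' @param loglik,n,n_events,converged,diagnostics Fit metadata; filled by
#'   [fit_gompertz()], optional for hand-built models.
#' @return An object of class `gompertz_ph`.
#' @examples
#' m <- gompertz_ph(rate = 1e-5, shape = 0.09, beta_age = 0.09,
#'                  beta = c(crp = 0.3))
#' gompertz_hazard(m, tibble::tibble(age = 60, crp = 1), t = 0)
#' @export
gompertz_ph <- function(rate, shape, beta_age, beta = numeric(),
                        loglik = NA_real_, n = NA_integer_,
                        n_events = NA_integer_, converged = NA,
                        diagnostics = list()) {
  stopifnot(is.numeric(rate), length(rate) == 1)
  if (!is.finite(rate) || rate <= 0) stop("rate must be finite and > 0", call. = FALSE)
  beta <- unlist(beta)
  if (length(beta) > 0 && (is.null(names(beta)) || any(names(beta) == ""))) {
    stop("biomarker coefficients must be named", call. = FALSE)
  }
  structure(
    list(rate = rate, shape = shape, beta_age = beta_age,
         beta = beta, biomarkers = names(beta),
         loglik = loglik, n = n, n_events = n_events,
         converged = converged, diagnostics = diagnostics),
    class = "gompertz_ph"
  )
}

# Linear predictor beta_age * age + sum_i beta_i x_i for each row of `data`.
# Errors name the biomarker columns the data lacks.
gompertz_lp <- function(model, data) {
  data <- tibble::as_tibble(data)
  if (!"age" %in% names(data)) stop("data must contain an 'age' column", call. = FALSE)
  missing <- setdiff(model$biomarkers, names(data))
  if (length(missing) > 0) {
    stop("data lacks biomarker column(s) required by the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- model$beta_age * data$age
  if (length(model$biomarkers) > 0) {
    X <- as.matrix(data[, model$biomarkers, drop = FALSE])
    lp <- lp + drop(X %*% model$beta)
  }
  lp
}

# (exp(shape t) - 1) / shape, continuous at shape = 0.
gompertz_phi <- function(t, shape) {
  if (shape == 0) t else expm1(shape * t) / shape
}

# d/d shape of gompertz_phi; series expansion near 0 avoids cancellation.
gompertz_dphi <- function(t, shape) {
  if (abs(shape) < 1e-6) {
    t^2 / 2 + shape * t^3 / 3 + shape^2 * t^4 / 8
  } else {
    (t * exp(shape * t) - gompertz_phi(t, shape)) / shape
  }
}

#' Gompertz PH hazard and cumulative hazard
#'
#' `gompertz_hazard()` evaluates the hazard \eqn{h(t)} and
#' `gompertz_cum_hazard()` the cumulative hazard
#' \eqn{H(t) = \int_0^t h(u)\,du = \mathrm{rate}\, e^{lp}
#'   (e^{\mathrm{shape}\,t} - 1)/\mathrm{shape}}
#' (with the exponential limit \eqn{\mathrm{rate}\, e^{lp} t} at shape = 0)
#' for each row of `data` at time `t` years after baseline.
#'
#' @param model A [gompertz_ph] model.
#' @param data Data frame with an `age` column and the model's biomarker
#'   columns.
#' @param t Time since baseline in years (scalar or one value per row);
#'   must be >= 0.
#' @return Numeric vector, one value per row of `data`; hazards are
#'   strictly positive.
#' @export
gompertz_hazard <- function(model, data, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lp <- gompertz_lp(model, data)
  model$rate * exp(lp + model$shape * t)
}

#' @rdname gompertz_hazard
#' @export
gompertz_cum_hazard <- function(model, data, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lp <- gompertz_lp(model, data)
  model$rate * exp(lp) * gompertz_phi(t, model$shape)
}

#' Right-censored Gompertz PH log-likelihood
#'
#' The standard censored survival log-likelihood
#' \eqn{\sum_i d_i \log h(t_i) - \sum_i H(t_i)} with `event` as the death
#' indicator, evaluated at the model's parameters on a cohort.
#'
#' @inheritParams gompertz_hazard
#' @param data Cohort with `age`, `time`, `event` and the model's
#'   biomarker columns.
#' @return A single finite number for valid parameters.
#' @export
gompertz_loglik <- function(model, data) {
  data <- validate_cohort(data, model$biomarkers)
  lp <- gompertz_lp(model, data)
  h_log <- log(model$rate) + lp + model$shape * data$time
  H <- model$rate * exp(lp) * gompertz_phi(data$time, model$shape)
  sum(data$event * h_log) - sum(H)
}

# Negative log-likelihood and gradient over theta = (log rate, shape?, betas?)
# with optional fixed shape / beta_age. Z is cbind(age, X); free_b indexes
# the columns of Z whose coefficients are optimized.
gompertz_nll <- function(theta, Z, time, event, fix_shape, fix_beta_age,
                         gradient = FALSE) {
  log_rate <- theta[1]
  i <- 2
  if (is.null(fix_shape)) {
    shape <- theta[i]; i <- i + 1
  } else shape <- fix_shape
  b <- numeric(ncol(Z))
  if (is.null(fix_beta_age)) {
    b[1] <- theta[i]; i <- i + 1
  } else b[1] <- fix_beta_age
  p_free <- length(theta) - i + 1
  if (p_free > 0) b[seq(2, 1 + p_free)] <- theta[i:length(theta)]

  lp <- drop(Z %*% b)
  H <- exp(log_rate + lp) * gompertz_phi(time, shape)
  ll <- sum(event * (log_rate + lp + shape * time)) - sum(H)
  if (!gradient) return(-ll)

  g <- numeric(length(theta))
  g[1] <- sum(event) - sum(H)
  j <- 2
  if (is.null(fix_shape)) {
    g[j] <- sum(event * time) - sum(exp(log_rate + lp) * gompertz_dphi(time, shape))
    j <- j + 1
  }
  resid <- event - H
  if (is.null(fix_beta_age)) {
    g[j] <- sum(resid * Z[, 1]); j <- j + 1
  }
  if (p_free > 0) {
    g[j:length(theta)] <- drop(crossprod(Z[, seq(2, 1 + p_free), drop = FALSE], resid))
  }
  -g
}

#' Fit a Gompertz proportional-hazards mortality model
#'
#' Maximum-likelihood fit of the Gompertz PH model to a right-censored
#' cohort, optimizing over (log rate, shape, beta_age, biomarker
#' coefficients). `rate` is parameterized on the log scale to enforce
#' positivity; `shape` is unconstrained (negative values allowed). The age
#' coefficient can be fixed at a given value — the protocol for the second,
#' biomarker-augmented model of a clock derivation, which shares the
#' age-only model's age coefficient while rate, shape and the biomarker
#' coefficients are re-estimated. Biomarkers enter on their native scale so
#' the derived clock coefficients keep their units.
#'
#' Initialization: shape 0.08 and beta_age 0.08 per year (a typical adult
#' Gompertz slope), biomarker coefficients 0, and log rate set to the
#' exponential-model MLE given those slopes. Optimization is BFGS with
#' analytic gradients, polished by a restart; convergence requires the
#' optimizer to report success and the per-subject-scaled gradient max-norm
#' to be at most 1e-4. Non-convergence is reported via `converged = FALSE`
#' and `diagnostics`, not an error.
#'
#' @param data Cohort tibble with `age`, `time`, `event` and biomarker
#'   columns; at least 2 events, no missing values.
#' @param biomarkers Character vector of biomarker columns to include
#'   (empty for the age-only model).
#' @param fix_beta_age Optional value at which the age coefficient is held
#'   fixed (appears exactly in the result).
#' @param fix_shape Optional fixed shape (e.g. 0 for an exponential fit).
#' @param control Passed to [stats::optim()]; defaults set
#'   `maxit = 2000, reltol = 1e-12`.
#' @return A fitted [gompertz_ph] object with `loglik`, `n`, `n_events`,
#'   `converged` and `diagnostics` (scaled gradient max-norm, optimizer
#'   counts, condition-number note for rank-deficient designs).
#' @examples
#' cohort <- simulate_cohort(
#'   n = 500,
#'   truth = gompertz_ph(2e-5, 0.09, 0.09, c(crp = 0.3)),
#'   biomarker_specs = list(crp = bm_normal(1, 1)), seed = 1)
#' fit_gompertz(cohort, "crp")
#' @export
fit_gompertz <- function(data, biomarkers = character(), fix_beta_age = NULL,
                         fix_shape = NULL, control = list()) {
  data <- validate_cohort(data, biomarkers)
  n <- nrow(data)
  n_events <- sum(data$event)
  if (n_events == 0) stop("no events: cannot fit a mortality model", call. = FALSE)
  if (n_events < 2) stop("need at least 2 events to fit", call. = FALSE)

  Z <- cbind(age = data$age,
             if (length(biomarkers) > 0) as.matrix(data[, biomarkers, drop = FALSE]))
  cond_note <- NULL
  if (length(biomarkers) > 0) {
    qrz <- qr(scale(Z, scale = FALSE))
    if (qrz$rank < ncol(Z)) {
      d <- abs(diag(qr.R(qrz)))
      cond_note <- paste0("design rank ", qrz$rank, " < ", ncol(Z),
                          "; |R| diagonal ratio ",
                          format(max(d) / max(min(d), .Machine$double.eps)))
      warning("biomarker design matrix is rank deficient (", cond_note,
              "); fit proceeds but coefficients are not identifiable",
              call. = FALSE)
    }
  }

  # initial values: field-typical Gompertz slope, exponential-MLE rate
  b0 <- c(if (is.null(fix_beta_age)) 0.08 else fix_beta_age,
          rep(0, length(biomarkers)))
  shape0 <- if (is.null(fix_shape)) 0.08 else fix_shape
  lp0 <- drop(Z %*% b0)
  log_rate0 <- log(n_events / sum(exp(lp0) * pmax(data$time, 1e-8)))
  theta0 <- c(log_rate0,
              if (is.null(fix_shape)) shape0,
              if (is.null(fix_beta_age)) 0.08,
              rep(0, length(biomarkers)))

  ctrl <- modifyList(list(maxit = 2000, reltol = 1e-12), control)
  fn <- function(th) gompertz_nll(th, Z, data$time, data$event, fix_shape, fix_beta_age)
  gr <- function(th) gompertz_nll(th, Z, data$time, data$event, fix_shape, fix_beta_age,
                                  gradient = TRUE)
  opt <- optim(theta0, fn, gr, method = "BFGS", control = ctrl)
  # restart once from the optimum; BFGS occasionally stops on a stale Hessian
  opt2 <- optim(opt$par, fn, gr, method = "BFGS", control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2

  th <- opt$par
  grad <- gr(th)
  grad_scaled <- max(abs(grad)) / n
  converged <- opt$convergence == 0 && is.finite(opt$value) && grad_scaled <= 1e-4

  i <- 2
  shape <- if (is.null(fix_shape)) { s <- th[i]; i <- i + 1; s } else fix_shape
  beta_age <- if (is.null(fix_beta_age)) { b <- th[i]; i <- i + 1; b } else fix_beta_age
  beta <- if (length(biomarkers) > 0) setNames(th[i:length(th)], biomarkers) else numeric()

  gompertz_ph(
    rate = exp(th[1]), shape = shape, beta_age = beta_age, beta = beta,
    loglik = -opt$value, n = n, n_events = n_events, converged = converged,
    diagnostics = list(grad_max_scaled = grad_scaled,
                       optim_convergence = opt$convergence,
                       counts = opt$counts,
                       fixed = list(beta_age = fix_beta_age, shape = fix_shape),
                       condition_note = cond_note)
  )
}

#' @export
print.gompertz_ph <- function(x, ...) {
  cat("Gompertz proportional-hazards model\n")
  cat(sprintf("  rate  = %.6g   shape = %.4f /yr   beta_age = %.4f /yr\n",
              x$rate, x$shape, x$beta_age))
  if (length(x$beta) > 0) {
    cat("  biomarker coefficients:\n")
    for (nm in names(x$beta)) cat(sprintf("    %-16s %+.5f\n", nm, x$beta[[nm]]))
  } else {
    cat("  (age-only model)\n")
  }
  if (is.finite(x$loglik)) {
    cat(sprintf("  loglik = %.3f on n = %d (%d events); converged: %s\n",
                x$loglik, x$n, x$n_events, x$converged))
  }
  invisible(x)
}

#' Tidy a fitted Gompertz PH model
#'
#' @param x A [gompertz_ph] object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.gompertz_ph <- function(x, ...) {
  tibble::tibble(
    term = c("rate", "shape", "age", names(x$beta)),
    estimate = c(x$rate, x$shape, x$beta_age, unname(x$beta))
  )
}

#' @rdname tidy.gompertz_ph
#' @return `glance()`: a one-row tibble with `loglik`, `n`, `n_events`,
#'   `converged`.
#' @export
glance.gompertz_ph <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, n_events = x$n_events,
                 converged = x$converged)
}
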