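test_that("hazard evaluates the Gompertz PH form", {
  # constant-hazard limit: rate 1, no covariates, shape 0
  m0 <- gompertz_ph(rate = 1, shape = 0, beta_age = 0)
  d0 <- tibble::tibble(age = 50)
  expect_equal(gompertz_hazard(m0, d0, t = 0), 1)
  expect_equal(gompertz_hazard(m0, d0, t = 7.3), 1)

  # direct scalar evaluation
  m1 <- gompertz_ph(rate = 1e-4, shape = 0.09, beta_age = 0)
  expect_equal(gompertz_hazard(m1, d0, t = 10), 1e-4 * exp(0.9))

  # age enters once, each biomarker once, multiplicatively on the log scale
  m2 <- gompertz_ph(rate = 2e-5, shape = 0.1, beta_age = 0.08,
                    beta = c(a = 0.5, b = -0.2))
  d2 <- tibble::tibble(age = 60, a = 1.2, b = 3)
  expect_equal(gompertz_hazard(m2, d2, t = 4),
               2e-5 * exp(0.08 * 60 + 0.5 * 1.2 - 0.2 * 3 + 0.1 * 4))
  expect_gt(gompertz_hazard(m2, d2, t = 0), 0)
})

test_that("hazard errors name the missing biomarker and reject negative t", {
  m <- gompertz_ph(1e-4, 0.1, 0.08, beta = c(crp = 0.3, alb = -0.1))
  expect_error(gompertz_hazard(m, tibble::tibble(age = 60, crp = 1), t = 0),
               "alb")
  expect_error(gompertz_hazard(m, tibble::tibble(age = 60, crp = 1, alb = 40),
                               t = -1), "t must be")
})

test_that("cumulative hazard matches closed forms and the shape->0 limit", {
  # exponential limit: shape 0, rate 0.02, lp 0, t 5 -> 0.1
  m0 <- gompertz_ph(rate = 0.02, shape = 0, beta_age = 0)
  d <- tibble::tibble(age = 30)
  expect_equal(gompertz_cum_hazard(m0, d, 5), 0.1)

  # shape -> 0 continuity against the exponential closed form
  meps <- gompertz_ph(rate = 0.02, shape = 1e-10, beta_age = 0)
  expect_equal(gompertz_cum_hazard(meps, d, 5),
               gompertz_cum_hazard(m0, d, 5), tolerance = 1e-8)

  # survival exp(-H) non-increasing in t for random parameter draws,
  # including negative shapes
  set.seed(42)
  for (r in 1:20) {
    m <- gompertz_ph(rate = exp(runif(1, -10, -2)),
                     shape = runif(1, -0.1, 0.2),
                     beta_age = runif(1, 0, 0.1),
                     beta = c(x = runif(1, -1, 1)))
    dd <- tibble::tibble(age = runif(1, 30, 80), x = rnorm(1))
    tt <- sort(runif(8, 0, 40))
    S <- exp(-gompertz_cum_hazard(m, dd[rep(1, 8), ], tt))
    expect_true(all(diff(S) <= 1e-14))
  }
})

test_that("censored log-likelihood equals the standard event/cumulative form", {
  # one subject, event at t=1, unit hazard: log(1) - 1
  m <- gompertz_ph(rate = 1, shape = 0, beta_age = 0)
  one <- tibble::tibble(age = 0, time = 1, event = 1)
  expect_equal(gompertz_loglik(m, one), -1)

  # all-censored cohort: -sum H(t_i)
  cens <- tibble::tibble(age = c(50, 60), time = c(5, 8), event = c(0, 0))
  m2 <- gompertz_ph(rate = 1e-4, shape = 0.09, beta_age = 0.05)
  expect_equal(gompertz_loglik(m2, cens),
               -sum(gompertz_cum_hazard(m2, cens, cens$time)))

  # 5-subject fixture against numerically integrated hazard
  m3 <- gompertz_ph(rate = 5e-5, shape = 0.11, beta_age = 0.07,
                    beta = c(crp = 0.4))
  fix <- tibble::tibble(age = c(45, 52, 60, 68, 75),
                        crp = c(0.2, -1, 0.5, 1.4, 0),
                        time = c(12, 3.5, 8, 0.7, 15),
                        event = c(1, 0, 1, 1, 0))
  expect_equal(gompertz_loglik(m3, fix), quad_loglik(m3, fix),
               tolerance = 1e-6)
})

test_that("maximum-likelihood fit recovers generating parameters", {
  truth <- gompertz_ph(rate = 1.2e-4, shape = 0.09, beta_age = 0.08,
                       beta = c(x1 = 0.5, x2 = -0.3))
  cohort <- simulate_cohort(
    20000, truth, list(x1 = bm_normal(0, 1), x2 = bm_normal(2, 0.8)),
    age_range = c(40, 80), horizon = 25, seed = 404)
  # roughly 30% censoring under this horizon
  expect_gt(mean(cohort$event), 0.5)
  fit <- fit_gompertz(cohort, c("x1", "x2"))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), unname(truth$beta), tolerance = 0.05)
  # MLE property: fitted optimum beats the generating parameters
  expect_gte(fit$loglik, gompertz_loglik(truth, cohort))
  # scaled gradient max-norm at the reported optimum
  expect_lte(fit$diagnostics$grad_max_scaled, 1e-4)
})

test_that("MLE dominates truth across seeds", {
  truth <- gompertz_ph(rate = 1e-4, shape = 0.1, beta_age = 0.06,
                       beta = c(x = 0.4))
  for (s in 1:3) {
    cohort <- simulate_cohort(1500, truth, list(x = bm_normal(0, 1)),
                              horizon = 20, seed = s)
    fit <- fit_gompertz(cohort, "x")
    expect_gte(fit$loglik, gompertz_loglik(truth, cohort))
  }
})

test_that("exponential submodel MLE equals events over person-time", {
  truth <- gompertz_ph(rate = 0.05, shape = 0, beta_age = 0)
  cohort <- simulate_cohort(2000, truth, list(), age_range = c(50, 70),
                            horizon = 15, seed = 11)
  fit <- fit_gompertz(cohort, fix_beta_age = 0, fix_shape = 0)
  expect_equal(fit$rate, sum(cohort$event) / sum(cohort$time),
               tolerance = 1e-6)
  expect_identical(fit$beta_age, 0)
  expect_identical(fit$shape, 0)
})

test_that("the age coefficient constraint is honoured exactly", {
  truth <- gompertz_ph(1e-4, 0.1, 0.07, c(x = 0.3))
  cohort <- simulate_cohort(3000, truth, list(x = bm_normal(0, 1)),
                            horizon = 20, seed = 5)
  m1 <- fit_gompertz(cohort)
  m2 <- fit_gompertz(cohort, "x", fix_beta_age = m1$beta_age)
  expect_identical(m2$beta_age, m1$beta_age)
  # rate, shape and the biomarker coefficient were re-estimated
  expect_false(isTRUE(all.equal(m2$rate, m1$rate)))
  expect_true(m2$converged)
})

test_that("degenerate fits are rejected or flagged", {
  no_events <- tibble::tibble(age = c(50, 60), time = c(5, 8), event = c(0, 0))
  expect_error(fit_gompertz(no_events), "no events")

  truth <- gompertz_ph(1e-4, 0.1, 0.07, c(x = 0.3))
  cohort <- simulate_cohort(500, truth, list(x = bm_normal(0, 1)),
                            horizon = 20, seed = 9)
  cohort$x_dup <- cohort$x  # rank-deficient design
  expect_warning(fit <- fit_gompertz(cohort, c("x", "x_dup")),
                 "rank deficient")
  expect_s3_class(fit, "gompertz_ph")
})

test_that("fit agrees with an independent Gompertz implementation", {
  skip_if_not_installed("flexsurv")
  truth <- gompertz_ph(2e-5, 0.09, 0.09, c(crp = 0.4))
  cohort <- simulate_cohort(4000, truth, list(crp = bm_normal(0.7, 1)),
                            horizon = 20, seed = 77)
  mine <- fit_gompertz(cohort, "crp")
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ age + crp,
                              data = cohort, dist = "gompertz")
  expect_equal(mine$rate, fs$res["rate", "est"], tolerance = 1e-2)
  expect_equal(mine$shape, fs$res["shape", "est"], tolerance = 1e-3)
  expect_equal(mine$beta_age, fs$res["age", "est"], tolerance = 1e-3)
  expect_equal(unname(mine$beta), fs$res["crp", "est"], tolerance = 5e-3)
  # the two optimizers stop at slightly different points on a flat ridge;
  # the likelihoods must agree and ours must not be worse
  expect_equal(mine$loglik, fs$loglik, tolerance = 1e-7)
  expect_gte(mine$loglik, fs$loglik - 1e-6)
})

test_that("tidy and glance expose the fitted parameters", {
  m <- gompertz_ph(1e-4, 0.1, 0.08, c(crp = 0.3), loglik = -12.3,
                   n = 10L, n_events = 4L, converged = TRUE)
  td <- tidy(m)
  expect_equal(td$term, c("rate", "shape", "age", "crp"))
  expect_equal(td$estimate[4], 0.3)
  gl <- glance(m)
  expect_equal(gl$n_events, 4L)
})
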