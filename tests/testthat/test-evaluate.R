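test_that("concordance handles perfect, imperfect and tied rankings", {
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  # brute-force over the 3 comparable pairs: (1,2) disc, (1,3) conc, (2,3) conc
  expect_equal(c_index(c(2, 3, 1), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  # all scores tied -> 0.5
  expect_equal(c_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_error(c_index(c(1, 2), c(5, 5), c(1, 1)), "comparable")
})

test_that("concordance agrees with the O(n^2) oracle on random data", {
  set.seed(77)
  for (r in 1:3) {
    n <- 200
    score <- sample(1:50, n, replace = TRUE)  # force ties
    time <- round(rexp(n, 0.1), 1)            # and tied times
    event <- rbinom(n, 1, 0.6)
    expect_equal(c_index(score, time, event),
                 brute_c_index(score, time, event), tolerance = 1e-12)
  }
})

test_that("rank properties of the concordance index", {
  set.seed(11)
  score <- rnorm(100); time <- rexp(100); event <- rbinom(100, 1, 0.5)
  ci <- c_index(score, time, event)
  # complement under score reversal (ties absent almost surely)
  expect_equal(c_index(-score, time, event), 1 - ci, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(c_index(exp(2 * score), time, event), ci, tolerance = 1e-12)
})

test_that("horizon AUC separates, excludes early-censored, matches the U-statistic", {
  # perfectly separating score
  d <- tibble::tibble(score = c(10, 9, 1, 2), time = c(2, 3, 20, 20),
                      event = c(1, 1, 0, 0))
  suppressWarnings({  # perfect separation triggers a glm warning
    expect_equal(horizon_auc(d$score, d$time, d$event, 10)$auc_rank, 1)
    expect_equal(horizon_auc(-d$score, d$time, d$event, 10)$auc_rank, 0)
  })

  # 30-subject fixture against explicit pair counting
  set.seed(8)
  n <- 30
  time <- rexp(n, 0.08); event <- rbinom(n, 1, 0.8)
  score <- time * -0.2 + rnorm(n)
  out <- horizon_auc(score, time, event, horizon = 10)
  death <- event == 1 & time <= 10
  usable <- death | time >= 10
  expect_equal(out$auc_rank, brute_auc(score[usable], as.integer(death[usable])))
  # logistic fitted-probability AUC equals the rank AUC (monotone link)
  expect_equal(out$auc_logistic, out$auc_rank, tolerance = 1e-12)
  expect_equal(out$n_excluded, sum(!usable))

  # degenerate outcome errors
  expect_error(horizon_auc(c(1, 2), c(1, 2), c(1, 1), horizon = 10),
               "degenerate")
})

test_that("Kaplan-Meier groups match the hand-computed product limit", {
  # high group: times 1,2,2,3,4,5 with events 1,1,0,1,0,1
  # S = 5/6, then 5/6*4/5 = 2/3, then 2/3*2/3 = 4/9, then 0 at t = 5
  d <- tibble::tibble(
    age = rep(60, 12),
    diff = rep(c(1, -1), each = 6),
    time = c(1, 2, 2, 3, 4, 5, rep(10, 6)),
    event = c(1, 1, 0, 1, 0, 1, rep(0, 6)))
  km <- km_quantile_groups(d, "diff", quantile = 0.5)
  hi <- km[km$group == "high", ]
  expect_equal(hi$surv, c(1, 5 / 6, 2 / 3, 4 / 9, 4 / 9, 0))
  expect_equal(hi$time, c(0, 1, 2, 3, 4, 5))
  # curves start at 1 and are non-increasing
  lo <- km[km$group == "low", ]
  expect_equal(lo$surv[1], 1)
  expect_true(all(diff(hi$surv) <= 0))
  # no events -> flat at 1
  expect_equal(lo$surv, rep(1, length(lo$surv)))
})

test_that("age-stratified KM uses within-stratum quantiles", {
  set.seed(12)
  d <- tibble::tibble(age = runif(400, 45, 85), diff = rnorm(400),
                      time = rexp(400, 0.05), event = rbinom(400, 1, 0.7))
  km <- km_quantile_groups(d, "diff", 0.25, age_breaks = c(45, 55, 65, 75, 85))
  expect_setequal(unique(km$stratum), c("45-55", "55-65", "65-75", "75-85"))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("Cox hazard ratio matches an independent Newton solver", {
  set.seed(21)
  n <- 120
  d <- tibble::tibble(age = runif(n, 40, 80), diff = rnorm(n, sd = 3),
                      time = rexp(n, 0.05), event = rbinom(n, 1, 0.7))
  out <- cox_hr_per_year(d, "diff", adjust = "age")
  beta_oracle <- newton_cox(cbind(d$diff, d$age), d$time, d$event)
  expect_equal(unname(log(out$hr)), beta_oracle[1], tolerance = 1e-6)
})

test_that("null Cox confidence intervals have near-nominal coverage", {
  covered <- 0
  set.seed(2024)
  for (s in 1:100) {
    cohort <- simulate_cohort(150, gompertz_ph(1e-3, 0.1, 0.05),
                              list(), horizon = 30, seed = 3000 + s)
    cohort$diff <- stats::rnorm(150)  # independent of the hazard
    out <- cox_hr_per_year(cohort, "diff", adjust = "age")
    if (out$conf_low <= 1 && out$conf_high >= 1) covered <- covered + 1
  }
  expect_gte(covered, 93)
})

test_that("stronger simulated effects raise the estimated hazard ratio", {
  hrs <- vapply(c(0.1, 0.3, 0.6), function(b) {
    truth <- gompertz_ph(1e-4, 0.1, 0.05, c(x = b))
    cohort <- simulate_cohort(4000, truth, list(x = bm_normal(0, 1)),
                              horizon = 20, seed = 61)
    cox_hr_per_year(cohort, "x", adjust = "age")$hr
  }, numeric(1))
  expect_true(all(diff(hrs) > 0))
})

test_that("PCA age reproduces exact age structure and the two-step oracle", {
  set.seed(31)
  n <- 300
  age <- runif(n, 40, 80)
  # biomarkers exact linear functions of age -> correlation 1
  d1 <- tibble::tibble(age = age, b1 = 2 * age + 1, b2 = -age / 3,
                       b3 = 0.5 * age)
  out1 <- pca_age(d1, c("b1", "b2", "b3"), n_components = 2)
  expect_equal(abs(stats::cor(out1$pca_age, age)), 1, tolerance = 1e-10)

  d2 <- tibble::tibble(age = age, b1 = age + rnorm(n), b2 = rnorm(n),
                       b3 = age / 2 + rnorm(n), b4 = rnorm(n),
                       b5 = rnorm(n), b6 = -age + rnorm(n))
  bms <- paste0("b", 1:6)
  out2 <- pca_age(d2, bms, n_components = 5)
  # two-step oracle: explicit SVD scores, then normal equations
  X <- scale(as.matrix(d2[, bms]))
  sv <- svd(X)
  scores <- (sv$u %*% diag(sv$d))[, 1:5]
  A <- cbind(1, scores)
  coefs <- solve(crossprod(A), crossprod(A, age))
  expect_equal(out2$pca_age, drop(A %*% coefs), tolerance = 1e-10)
  # invariant to biomarker column order
  out3 <- pca_age(d2, rev(bms), n_components = 5)
  expect_equal(out3$pca_age, out2$pca_age, tolerance = 1e-8)
  expect_warning(pca_age(d1, c("b1", "b2", "b3"), n_components = 5),
                 "n_components")
})

test_that("Mahalanobis distance matches the explicit solve oracle", {
  set.seed(41)
  n <- 100; p <- 4
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) + diag(p)
  X <- matrix(rnorm(n * p), n) %*% chol(Sigma)
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- paste0("b", 1:p)
  mu <- colMeans(X); S <- stats::cov(X)
  out <- mahalanobis_mds(d, names(d))
  oracle <- apply(X, 1, function(x) sqrt(drop(t(x - mu) %*% solve(S, x - mu))))
  expect_equal(out$mds, unname(oracle), tolerance = 1e-10)
  # x at the reference mean -> 0
  d0 <- tibble::as_tibble(as.data.frame(rbind(mu)))
  names(d0) <- names(d)
  expect_equal(mahalanobis_mds(d0, names(d), center = mu, covariance = S)$mds,
               0, tolerance = 1e-10)
  # identity covariance -> Euclidean distance
  out_e <- mahalanobis_mds(d, names(d), center = rep(0, p),
                           covariance = diag(p))
  expect_equal(out_e$mds, unname(sqrt(rowSums(X^2))), tolerance = 1e-10)
  # singular covariance is ridge-regularized with a warning
  d$b5 <- d$b1
  expect_warning(mahalanobis_mds(d, c(names(d))), "singular")
})

test_that("a biomarker-informed clock out-discriminates age alone", {
  rec <- run_recovery(n = 6000, seed = 14)
  pred <- predict_bioage(rec$cohort, rec$clock)
  c_clock <- c_index(pred$bioage, pred$time, pred$event)
  c_age <- c_index(pred$age, pred$time, pred$event)
  expect_gte(c_clock, c_age)
})

test_that("evaluate_clocks reports one metrics row and one KM set per clock", {
  rec <- run_recovery(n = 3000, seed = 16)
  clock2 <- bioage_clock(c(creatinine = 1), constant = 0)
  rep_ <- evaluate_clocks(rec$cohort,
                          list(derived = rec$clock, creat_only = clock2),
                          horizon = 10)
  expect_equal(nrow(rep_$metrics), 2)
  expect_setequal(names(rep_$km), c("derived", "creat_only"))
  expect_true(all(rep_$metrics$c_index > 0 & rep_$metrics$c_index < 1))
  expect_true(all(rep_$metrics$auc > 0 & rep_$metrics$auc < 1))
  expect_identical(tidy(rep_), rep_$metrics)
})
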