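# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, quadrature, explicit
# linear algebra, and a from-scratch Newton solver for the Cox model.

# O(n^2) concordance: comparable pair = strictly earlier time with an event;
# score ties count 0.5.
brute_c_index <- function(score, time, event) {
  conc <- 0; comp <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        comp <- comp + 1
        if (score[i] > score[j]) conc <- conc + 1
        else if (score[i] == score[j]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}

# censored log-likelihood with the cumulative hazard obtained by numerical
# quadrature of the hazard function, not the closed form
quad_loglik <- function(model, data) {
  ll <- 0
  for (i in seq_len(nrow(data))) {
    row <- data[i, , drop = FALSE]
    h <- function(u) gompertz_hazard(model, row, u)
    H <- stats::integrate(function(u) vapply(u, h, numeric(1)),
                          0, row$time, rel.tol = 1e-10)$value
    ll <- ll + data$event[i] * log(h(row$time)) - H
  }
  ll
}

# Mann-Whitney U-statistic AUC by explicit pair counting
brute_auc <- function(score, y) {
  s1 <- score[y == 1]; s0 <- score[y == 0]
  u <- 0
  for (a in s1) for (b in s0) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(s1) * length(s0))
}

# Newton-Raphson maximization of the Cox partial likelihood with Breslow
# tie handling, independent of survival::coxph
newton_cox <- function(X, time, event, n_iter = 30) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  for (it in seq_len(n_iter)) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    U <- rep(0, ncol(X)); I <- matrix(0, ncol(X), ncol(X))
    for (k in unique(time[event == 1])) {
      risk <- time >= k
      dk <- which(time == k & event == 1)
      S0 <- sum(w[risk])
      S1 <- colSums(X[risk, , drop = FALSE] * w[risk])
      S2 <- t(X[risk, , drop = FALSE]) %*% (X[risk, , drop = FALSE] * w[risk])
      d <- length(dk)
      U <- U + colSums(X[dk, , drop = FALSE]) - d * S1 / S0
      I <- I + d * (S2 / S0 - tcrossprod(S1 / S0))
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# standard light-truth recovery experiment shared by several tests
run_recovery <- function(n = 20000, seed = 1, beta1 = 0.09) {
  cfg <- make_light_truth(beta1 = beta1)
  cohort <- do.call(simulate_cohort, c(list(n = n, seed = seed), cfg))
  m1 <- fit_gompertz(cohort)
  m2 <- fit_gompertz(cohort, c("creatinine", "glucose", "log_crp"),
                     fix_beta_age = m1$beta_age)
  list(cohort = cohort, m1 = m1, m2 = m2,
       clock = derive_clock(cohort, m1, m2))
}

light_ratios <- c(creatinine = 8.3313, glucose = 0.8270, log_crp = 5.7305)
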