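test_that("with alpha = 1 and no covariates the MLE is the exponential closed form", {
  set.seed(71)
  time <- rexp(400, rate = 0.5)
  cens <- time > 3
  obs <- pmin(time, 3)
  status <- as.integer(!cens)
  # exponential MLE: beta-hat = total time / events, with alpha fixed at 1
  beta_hat <- sum(obs) / sum(status)
  ll_prof <- function(b) weibull_cox_loglik(obs, status, NULL, 1, b)
  opt <- optimize(ll_prof, c(0.1, 20), maximum = TRUE)
  expect_equal(opt$maximum, beta_hat, tolerance = 1e-4)
  # full fit should land near alpha = 1, beta = beta_hat
  fit <- fit_weibull_cox(obs, status)
  expect_lt(abs(fit$alpha - 1), 3 * fit$se[["alpha"]])
  expect_lt(abs(fit$beta - beta_hat), 3 * fit$se[["beta"]])
})

test_that("hazard, survival and cumulative hazard are mutually consistent", {
  fit <- list(alpha = 1.7, beta = 2.3, gamma = c(a = 0.4))
  th <- 1.2
  tg <- seq(0.2, 5, by = 0.2)
  cv <- survival_curve(fit, tg, theta = th)
  expect_equal(cv$survival[1L], exp(-cv$cumhaz[1L]))
  expect_equal(cv$cumhaz, -log(cv$survival))
  expect_true(all(diff(cv$survival) < 0))
  # h(t) = -d/dt log R(t), numerically
  eps <- 1e-5
  num_h <- vapply(tg, function(t) {
    (log(survival_curve(fit, t - eps, th)$survival) -
       log(survival_curve(fit, t + eps, th)$survival)) / (2 * eps)
  }, numeric(1))
  expect_equal(cv$hazard, num_h, tolerance = 1e-6)
  # a larger hazard multiplier lowers survival pointwise
  cv0 <- survival_curve(fit, tg, theta = 0)
  expect_true(all(cv$survival < cv0$survival))
})

test_that("closed-form moments agree with quadrature to 1e-6 relative error", {
  cases <- list(list(alpha = 1, beta = 2, gamma = numeric(0), theta = NULL),
                list(alpha = 2, beta = 1, gamma = numeric(0), theta = NULL),
                list(alpha = 2.6, beta = 0.8, gamma = c(0.5), theta = 0.7),
                list(alpha = 0.9, beta = 3, gamma = c(-0.4, 0.2),
                     theta = c(1, 2)))
  for (cs in cases) {
    mom <- weibull_cox_moments(cs, cs$theta)
    lp <- if (length(cs$gamma)) sum(cs$gamma * cs$theta) else 0
    dens <- function(t) (cs$alpha / t) * (t / cs$beta)^cs$alpha * exp(lp) *
      exp(-(t / cs$beta)^cs$alpha * exp(lp))
    m1 <- integrate(function(t) t * dens(t), 0, Inf, rel.tol = 1e-10)$value
    m2 <- integrate(function(t) t^2 * dens(t), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(mom$mean, m1, tolerance = 1e-6)
    expect_equal(mom$variance, m2 - m1^2, tolerance = 1e-6)
  }
  # alpha = 1, gamma = 0: exponential mean beta, variance beta^2
  mom <- weibull_cox_moments(list(alpha = 1, beta = 2, gamma = numeric(0)))
  expect_equal(mom$mean, 2)
  expect_equal(mom$variance, 4)
  # alpha = 2, beta = 1: mean Gamma(1.5)
  mom2 <- weibull_cox_moments(list(alpha = 2, beta = 1, gamma = numeric(0)))
  expect_equal(mom2$mean, gamma(1.5))
})

test_that("negative coefficients make the mean increase in theta", {
  fit <- list(alpha = 1.5, beta = 1, gamma = c(-0.8))
  means <- vapply(seq(0, 3, by = 0.5),
                  function(th) weibull_cox_moments(fit, th)$mean, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("parameter recovery on synthetic right-censored data (n = 500)", {
  set.seed(72)
  n <- 500
  X <- cbind(z = runif(n))
  true <- list(alpha = 2, beta = 1, gamma = 0.5)
  # inverse-transform sampling from the proportional-hazards Weibull
  u <- runif(n)
  t_true <- true$beta * (-log(u) * exp(-true$gamma * X[, 1L]))^(1 / true$alpha)
  cens_at <- 1.5
  status <- as.integer(t_true <= cens_at)
  obs <- pmin(t_true, cens_at)
  fit <- fit_weibull_cox(obs, status, X)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - true$alpha), 3 * fit$se[["alpha"]])
  expect_lt(abs(fit$beta - true$beta), 3 * fit$se[["beta"]])
  expect_lt(abs(fit$gamma[["z"]] - true$gamma), 3 * fit$se[["z"]])
  # duplicating the data doubles the log-likelihood, same estimates
  fit2 <- fit_weibull_cox(c(obs, obs), c(status, status), rbind(X, X))
  expect_equal(fit2$loglik, 2 * fit$loglik, tolerance = 1e-4)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-4)
  expect_error(fit_weibull_cox(obs, rep(0L, n)), "at least one")
})

test_that("the MLE agrees with the survreg Weibull fit (independent oracle)", {
  skip_if_not_installed("survival")
  set.seed(73)
  n <- 300
  X <- cbind(z = runif(n))
  u <- runif(n)
  t_true <- 1.2 * (-log(u) * exp(-0.7 * X[, 1L]))^(1 / 1.8)
  status <- as.integer(t_true <= 1.2)
  obs <- pmin(t_true, 1.2)
  fit <- fit_weibull_cox(obs, status, X)
  sr <- survival::survreg(survival::Surv(obs, status) ~ X, dist = "weibull")
  # AFT -> proportional hazards mapping
  expect_equal(fit$alpha, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(fit$beta, unname(exp(coef(sr)[1L])), tolerance = 1e-3)
  expect_equal(unname(fit$gamma), unname(-coef(sr)[-1L] / sr$scale),
               tolerance = 1e-3)
  expect_equal(fit$loglik, sr$loglik[2L], tolerance = 1e-6)
})
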