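# Right-censored Weibull proportional-hazards likelihood for hitting times:
# baseline Weibull(shape alpha, scale beta) hazard multiplied by
# exp(gamma . theta). MLE over (log alpha, log beta, gamma) with Wald
# inference from the observed information.

#' Weibull proportional-hazards log-likelihood
#'
#' Density `f(t|theta) = (alpha/t) (t/beta)^alpha e^{g} exp(-(t/beta)^alpha e^{g})`
#' and survival `R(t|theta) = exp(-(t/beta)^alpha e^{g})` with linear
#' predictor `g = gamma . theta`. Events contribute `log f`, censored
#' observations `log R`.
#'
#' @param time positive observation times (hitting or censoring).
#' @param status 1 for an observed hit, 0 for right-censored.
#' @param X covariate matrix (rows = observations), or `NULL` for the
#'   baseline Weibull model.
#' @param alpha,beta Weibull shape and scale, `> 0`.
#' @param gamma coefficient vector (length = columns of `X`).
#' @return scalar log-likelihood.
#' @export
weibull_cox_loglik <- function(time, status, X = NULL, alpha, beta,
                               gamma = numeric(0)) {
  if (any(time <= 0)) stop("times must be positive")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  lp <- if (is.null(X) || length(gamma) == 0L) 0 else as.vector(X %*% gamma)
  logH <- alpha * (log(time) - log(beta)) + lp       # log cumulative hazard
  H <- exp(logH)
  sum(status * (log(alpha) - log(time) + logH)) - sum(H)
}

#' Fit the Weibull proportional-hazards model
#'
#' Maximum likelihood over `(log alpha, log beta, gamma)` by BFGS; standard
#' errors from the observed information (numerically differentiated
#' Hessian), with the delta method for `alpha` and `beta` on their natural
#' scale. Wald p-values test each coefficient against 0.
#'
#' @param time positive observation times.
#' @param status 1 = event (hit), 0 = right-censored.
#' @param X covariate matrix or data frame (covariates on natural scale), or
#'   `NULL` for the baseline Weibull fit.
#' @param standardize z-score the covariates before fitting (coefficients
#'   are reported on the standardized scale).
#' @return object of class `weibull_cox_fit`: `alpha`, `beta`, `gamma`,
#'   `se` (on alpha/beta/gamma scale), `p_value` (Wald, for gamma),
#'   `loglik`, `vcov` (on the optimization scale), `converged`.
#' @export
fit_weibull_cox <- function(time, status, X = NULL, standardize = FALSE) {
  status <- as.integer(status)
  if (sum(status) < 1L) stop("at least one observed event is required")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (standardize) X <- scale(X)
    if (qr(cbind(1, X))$rank < ncol(X) + 1L)
      stop("covariates are collinear-degenerate")
  }
  p <- if (is.null(X)) 0L else ncol(X)
  nll <- function(par) {
    val <- weibull_cox_loglik(time, status, X, exp(par[1L]), exp(par[2L]),
                              if (p) par[-(1:2)] else numeric(0))
    if (!is.finite(val)) return(1e10)
    -val
  }
  start <- c(0, log(mean(time)), rep(0, p))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  hess <- stats::optimHess(opt$par, nll)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, 2L + p, 2L + p))
  se_t <- sqrt(pmax(diag(vc), 0))
  alpha <- exp(opt$par[1L]); beta <- exp(opt$par[2L])
  gamma <- if (p) opt$par[-(1:2)] else numeric(0)
  se <- c(alpha = alpha * se_t[1L], beta = beta * se_t[2L],
          if (p) stats::setNames(se_t[-(1:2)], colnames(X)))
  pval <- if (p) 2 * stats::pnorm(-abs(gamma / se_t[-(1:2)])) else numeric(0)
  structure(list(
    alpha = alpha, beta = beta,
    gamma = if (p) stats::setNames(gamma, colnames(X)) else numeric(0),
    se = se,
    p_value = if (p) stats::setNames(pval, colnames(X)) else numeric(0),
    loglik = -opt$value, vcov = vc, converged = opt$convergence == 0L,
    n = length(time), n_events = sum(status), standardize = standardize
  ), class = "weibull_cox_fit")
}

#' @export
print.weibull_cox_fit <- function(x, ...) {
  cat("Weibull proportional-hazards fit (", x$n_events, "events /", x$n,
      "observations )\n")
  cat("  shape alpha =", signif(x$alpha, 5), " scale beta =",
      signif(x$beta, 5), "\n")
  if (length(x$gamma)) {
    tab <- data.frame(coef = x$gamma,
                      se = x$se[names(x$gamma)],
                      p = signif(x$p_value, 3))
    print(tab)
  }
  cat("  log-likelihood:", signif(x$loglik, 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' Closed-form mean and variance of the hitting time
#'
#' `E tau(theta) = beta e^{-gamma.theta/alpha} Gamma(1 + 1/alpha)` and
#' `Var tau(theta) = beta^2 e^{-2 gamma.theta/alpha}
#'   (Gamma(1 + 2/alpha) - Gamma(1 + 1/alpha)^2)`; with `gamma < 0` both
#' increase exponentially in theta.
#'
#' @param fit a `weibull_cox_fit`, or a list with `alpha`, `beta`, `gamma`.
#' @param theta covariate vector (default none).
#' @return list with `mean` and `variance`.
#' @export
weibull_cox_moments <- function(fit, theta = NULL) {
  lp <- if (is.null(theta) || !length(fit$gamma)) 0 else sum(fit$gamma * theta)
  scale_eff <- fit$beta * exp(-lp / fit$alpha)
  g1 <- gamma(1 + 1 / fit$alpha)
  g2 <- gamma(1 + 2 / fit$alpha)
  list(mean = scale_eff * g1, variance = scale_eff^2 * (g2 - g1^2))
}

#' Survival and cumulative-hazard curves
#'
#' Tabulates `R(t, theta) = exp(-(t/beta)^alpha e^{gamma.theta})` and
#' `H(t, theta) = (t/beta)^alpha e^{gamma.theta}` on a time grid.
#'
#' @param fit a `weibull_cox_fit` (or compatible list).
#' @param times positive time grid.
#' @param theta covariate vector (default baseline).
#' @return data frame with columns `time`, `survival`, `cumhaz`, `hazard`.
#' @export
survival_curve <- function(fit, times, theta = NULL) {
  if (any(times < 0)) stop("times must be >= 0")
  lp <- if (is.null(theta) || !length(fit$gamma)) 0 else sum(fit$gamma * theta)
  H <- (times / fit$beta)^fit$alpha * exp(lp)
  h <- (fit$alpha / times) * (times / fit$beta)^fit$alpha * exp(lp)
  data.frame(time = times, survival = exp(-H), cumhaz = H, hazard = h)
}

#' Fit the Weibull-Cox model to a sweep dataset
#'
#' Convenience wrapper: takes the hitting-time table produced by
#' [run_core_sweep()] / [run_expanded_sweep()], uses finite `tau` as events
#' and budget-censored rows at their censor time.
#'
#' @param sweep a `sweep_dataset`.
#' @param covariates column names to use as covariates.
#' @param standardize passed to [fit_weibull_cox()].
#' @return a `weibull_cox_fit`.
#' @export
fit_sweep_survival <- function(sweep, covariates = c("n", "k"),
                               standardize = FALSE) {
  time <- ifelse(sweep$censored, sweep$censor_time, sweep$tau)
  keep <- is.finite(time) & time > 0
  fit_weibull_cox(time[keep], as.integer(!sweep$censored[keep]),
                  as.matrix(sweep[keep, covariates, drop = FALSE]),
                  standardize = standardize)
}
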