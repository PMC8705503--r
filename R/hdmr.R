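# High dimensional model representation: least-squares projection of an
# input-output map onto mean-zero, mutually orthogonal component functions
# f0 + sum_i f_i + sum_{i<j} f_ij under a product input measure, with
# variance-based sensitivity indices S_u = Var(f_u) / Var(y).
#
# Bases: orthonormal polynomial contrasts for discrete (gridded) inputs,
# orthonormal shifted-Legendre polynomials for continuous inputs (uniform
# marginals); second-order terms are tensor products, hierarchically
# orthogonal by construction.

legendre_shifted <- function(u, degree) {
  # orthonormal on [0, 1] under the uniform measure
  polys <- list(
    function(u) sqrt(3) * (2 * u - 1),
    function(u) sqrt(5) * (6 * u^2 - 6 * u + 1),
    function(u) sqrt(7) * (20 * u^3 - 30 * u^2 + 12 * u - 1)
  )
  vapply(seq_len(degree), function(d) polys[[d]](u), numeric(length(u)))
}

# per-variable basis: returns matrix of basis values plus an evaluator
hdmr_basis <- function(x, discrete, degree, domain = NULL) {
  if (discrete) {
    lev <- sort(unique(x))
    L <- length(lev)
    if (L < 2L) return(NULL)
    C <- stats::contr.poly(L) * sqrt(L)    # orthonormal under uniform levels
    B <- C[match(x, lev), , drop = FALSE]
    list(B = B, eval = function(z) C[match(z, lev), , drop = FALSE],
         type = "discrete", levels = lev, df = L - 1L)
  } else {
    if (is.null(domain)) domain <- range(x)
    if (diff(domain) <= 0) return(NULL)
    u <- (x - domain[1L]) / diff(domain)
    deg <- min(degree, 3L)
    B <- legendre_shifted(u, deg)
    list(B = B,
         eval = function(z) legendre_shifted((z - domain[1L]) / diff(domain), deg),
         type = "continuous", domain = domain, df = deg)
  }
}

#' Fit an HDMR expansion
#'
#' Projects observations `y` on inputs `X` onto a first- or second-order
#' HDMR under the product input measure of the design (uniform over grid
#' levels for discrete inputs, uniform over `domains` for continuous ones).
#' Component variances are sums of squared coefficients of the orthonormal
#' bases; sensitivity indices divide by the empirical outcome variance.
#'
#' @param X data frame of inputs.
#' @param y numeric outcome, one value per row of `X`.
#' @param order expansion order, 1 or 2.
#' @param degree polynomial degree for continuous inputs (max 3).
#' @param discrete character vector naming discrete inputs; by default any
#'   input with at most 8 distinct values is treated as discrete (gridded).
#' @param domains optional named list of `c(min, max)` for continuous
#'   inputs; defaults to the observed range.
#' @return object of class `hdmr_model`: `f0`, per-term coefficient blocks,
#'   sensitivity indices `S`, component variances `sigma2`, the fraction of
#'   outcome variance captured by the expansion (`explained`), and fitted
#'   values.
#' @examples
#' set.seed(1)
#' X <- data.frame(a = runif(300), b = runif(300))
#' fit <- fit_hdmr(X, X$a + X$b, order = 2)
#' fit$S  # ~ (0.5, 0.5, ~0)
#' @export
fit_hdmr <- function(X, y, order = 2L, degree = 3L, discrete = NULL,
                     domains = NULL) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) < 10L) stop("too few samples for an HDMR fit")
  order <- as.integer(order)
  if (!order %in% 1:2) stop("order must be 1 or 2")
  vars <- names(X)
  if (is.null(discrete))
    discrete <- vars[vapply(X, function(col) length(unique(col)) <= 8L, logical(1))]
  bases <- list()
  for (v in vars) {
    b <- hdmr_basis(if (is.numeric(X[[v]])) X[[v]] else as.numeric(factor(X[[v]])),
                    v %in% discrete, degree, domains[[v]])
    if (!is.null(b)) bases[[v]] <- b
  }
  if (length(bases) == 0L) stop("no input varies: nothing to decompose")

  blocks <- list()
  for (v in names(bases)) blocks[[v]] <- bases[[v]]$B
  if (order >= 2L && length(bases) >= 2L) {
    nm <- names(bases)
    for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
      Bi <- bases[[nm[i]]]$B; Bj <- bases[[nm[j]]]$B
      cols <- do.call(cbind, lapply(seq_len(ncol(Bi)), function(a) Bi[, a] * Bj))
      blocks[[paste(nm[i], nm[j], sep = ":")]] <- cols
    }
  }
  design <- cbind(`(f0)` = 1, do.call(cbind, blocks))
  block_idx <- split(seq_len(ncol(design) - 1L) + 1L,
                     rep(names(blocks), vapply(blocks, ncol, integer(1))))
  # joint minimum-norm least squares via truncated SVD: aliased basis
  # directions (e.g. after conditioning on hits) are dropped rather than
  # inflated into near-dependent coefficients
  sv <- svd(design)
  keep <- sv$d > max(sv$d) * 1e-8
  if (!all(keep))
    warning("rank-deficient HDMR design (", sum(!keep),
            " aliased basis directions truncated)")
  coefs <- as.vector(sv$v[, keep, drop = FALSE] %*%
                       (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
  names(coefs) <- colnames(design)
  var_y <- stats::var(y)
  # component variances under the sample measure: on a balanced product
  # design this equals the sum of squared coefficients of the orthonormal
  # basis; on unbalanced samples it keeps sparsely observed levels from
  # receiving more variance weight than the data supports
  sigma2 <- vapply(block_idx, function(ix) {
    g <- design[, ix, drop = FALSE] %*% coefs[ix]
    stats::var(as.vector(g))
  }, numeric(1))
  S <- if (var_y > 0) sigma2 / var_y else sigma2 * 0
  fitted <- as.vector(design %*% coefs)
  explained <- if (var_y > 0) stats::var(fitted) / var_y else 0
  structure(list(
    f0 = unname(coefs[1L]), coefficients = coefs, blocks = block_idx,
    bases = bases, order = order, S = S, sigma2 = sigma2,
    var_y = var_y, explained = explained, fitted = fitted,
    residuals = y - fitted, n = length(y)
  ), class = "hdmr_model")
}

#' @export
print.hdmr_model <- function(x, ...) {
  cat("HDMR model (order", x$order, ",", x$n, "samples )\n")
  cat("  f0 =", signif(x$f0, 5), " explained variance =",
      signif(100 * x$explained, 4), "%\n  sensitivity indices:\n")
  print(signif(sort(x$S, decreasing = TRUE), 4))
  invisible(x)
}

#' Evaluate a first-order HDMR component function
#'
#' @param model an `hdmr_model`.
#' @param var input name.
#' @param grid points at which to evaluate `f_var`; defaults to the grid
#'   levels (discrete) or 101 points over the domain (continuous).
#' @return data frame with columns `x` and `f` (mean-zero component value).
#' @export
hdmr_component <- function(model, var, grid = NULL) {
  b <- model$bases[[var]]
  if (is.null(b)) stop("no component for input ", var)
  if (is.null(grid))
    grid <- if (b$type == "discrete") b$levels
            else seq(b$domain[1L], b$domain[2L], length.out = 101L)
  vals <- b$eval(grid) %*% model$coefficients[model$blocks[[var]]]
  data.frame(x = grid, f = as.vector(vals))
}

sweep_inputs <- function(sweep) {
  intersect(c("n", "terminus", "kdecay", "fclay", "p_clay"), names(sweep))
}

#' HDMR of the hitting indicator (hitting probability)
#'
#' Fits an HDMR to the per-run finite-hit indicator of a sweep dataset: a
#' variance decomposition of the probability of hitting over the swept
#' parameters. The curvature input enters through its grid level (the
#' terminus value); with orthonormal level contrasts the indices are
#' invariant to any monotone recoding of the grid.
#'
#' @param sweep a `sweep_dataset`.
#' @param order expansion order.
#' @param inputs input columns; defaults to the theta columns present.
#' @return an `hdmr_model` (outcome in \{0, 1\}).
#' @export
classify_hitting <- function(sweep, order = 2L, inputs = sweep_inputs(sweep)) {
  y <- as.numeric(!sweep$censored)
  fit_hdmr(sweep[inputs], y, order = order,
           domains = list(kdecay = c(0, 1), fclay = c(0, 1), p_clay = c(0, 1)))
}

#' HDMR of the hitting time on the finite-hit subsample
#'
#' Fits an HDMR of the hitting time tau using only runs that hit (the
#' conditioning on hitting is part of the construction: the regressor
#' describes how long hits take, given that they occur).
#'
#' @inheritParams classify_hitting
#' @return an `hdmr_model` over the finite-hit rows.
#' @export
regress_hitting_time <- function(sweep, order = 2L,
                                 inputs = sweep_inputs(sweep)) {
  fin <- !sweep$censored & is.finite(sweep$tau)
  if (sum(fin) < 10L) stop("too few finite hitting times for a regressor")
  fit_hdmr(sweep[fin, inputs, drop = FALSE], sweep$tau[fin], order = order,
           domains = list(kdecay = c(0, 1), fclay = c(0, 1), p_clay = c(0, 1)))
}
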