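# Mean-field mass-action reduction of the reaction network. State: one
# concentration per single-strand sequence plus one per canonical duplex
# (dimension 4^n + 4^n/2 = 3*4^n/2). The replication term keeps the
# self-pair exclusion of the stochastic propensity,
# a f(x) s(x,y) [x]([y] - I(x=y)), the literal mass-action translation of
# N(x)(N(y) - I(x=y)); with it the single-molecule state concentrated on a
# high-fidelity sequence is an exact zero of the vector field.

#' Build the mean-field ODE system
#'
#' Assembles the mass-action vector field of duplex formation
#' (`kds [x][xc]`), dissociation (`kss [xxc]`) and template-directed
#' polymerization (ordered pairs at rate `a f(x) s(x,y) [x]([y]-I(x=y))`,
#' offspring distributed over sequences by the exact mutation kernel), with
#' optional decay and clay channels.
#'
#' @param ls an `rna_landscape` (enumeration-capped; intended for small n).
#' @param rates a `reaction_rates`; decay/clay terms enter only when
#'   `include_decay_clay = TRUE` (the stability analysis concerns the core
#'   network).
#' @param include_decay_clay include decay and clay channels.
#' @return object of class `ode_system` with fields `n`, `dim`, `species`
#'   (labels), `field(state)` and `jacobian(state)` (central differences).
#' @export
build_mean_field <- function(ls, rates = reaction_rates(),
                             include_decay_clay = FALSE) {
  stopifnot(inherits(ls, "rna_landscape"))
  n <- ls$n
  check_enum_cap(n, min(default_enum_cap(), 3L))
  mE <- 4^n
  comp <- ls$comp
  canon <- which(0:(mE - 1L) < comp) # 1-based indices of canonical duplex codes
  nd <- length(canon)
  dim <- mE + nd
  # precompute offspring kernels grouped by fidelity value
  pvals <- sort(unique(ls$Pv))
  Kmats <- lapply(pvals, function(p) {
    if (p >= 1) {
      M <- matrix(0, mE, mE)                    # M[y, z] = Q((.,y), z)
      M[cbind(seq_len(mE), comp + 1L)] <- 1
      M
    } else {
      wK <- p^(n - (0:n)) * ((1 - p) / 3)^(0:n)
      matrix(wK[ls$D[comp + 1L, ] + 1L], mE, mE)
    }
  })
  pgroup <- match(ls$Pv, pvals)

  field <- function(state) {
    cs <- state[seq_len(mE)]
    cd <- state[mE + seq_len(nd)]
    ds <- numeric(mE)
    dd <- numeric(nd)
    # duplex formation / dissociation
    x1 <- canon; x2 <- comp[canon] + 1L
    flux_ds <- rates$kds * cs[x1] * cs[x2]
    flux_ss <- rates$kss * cd
    ds[x1] <- ds[x1] - flux_ds + flux_ss
    ds[x2] <- ds[x2] - flux_ds + flux_ss
    dd <- flux_ds - flux_ss
    # replication: pair fluxes with self-pair exclusion
    Fc <- ls$Fv * cs
    W <- ls$a * outer(Fc, cs) * ls$Sm
    diag(W) <- ls$a * ls$Fv * ls$sdiag * cs * (cs - 1)
    for (g in seq_along(pvals)) {
      rows <- pgroup == g
      if (!any(rows)) next
      tw <- colSums(W[rows, , drop = FALSE])    # template weights
      ds <- ds + as.vector(crossprod(Kmats[[g]], tw))
    }
    if (include_decay_clay) {
      ds <- ds - rates$kdecay * cs
      ds <- ds + rates$kclay_o / mE
      if (rates$kclay_p > 0) {
        wK <- rates$p_clay^(n - (0:n)) * ((1 - rates$p_clay) / 3)^(0:n)
        Mc <- if (rates$p_clay >= 1) {
          M <- matrix(0, mE, mE); M[cbind(seq_len(mE), comp + 1L)] <- 1; M
        } else matrix(wK[ls$D[comp + 1L, ] + 1L], mE, mE)
        ds <- ds + as.vector(crossprod(Mc, rates$kclay_p * cs))
      }
    }
    c(ds, dd)
  }
  jacobian <- function(state, h = 1e-6) {
    J <- matrix(0, dim, dim)
    for (j in seq_len(dim)) {
      e <- numeric(dim); e[j] <- h
      J[, j] <- (field(state + e) - field(state - e)) / (2 * h)
    }
    J
  }
  species <- c(rna_decode(0:(mE - 1L), n),
               paste0(rna_decode(canon - 1L, n), ":",
                      rna_decode(comp[canon], n)))
  structure(list(n = n, dim = dim, mE = mE, canon = canon,
                 species = species, field = field, jacobian = jacobian,
                 ls = ls, rates = rates),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("Mean-field ODE system: n =", x$n, ", dimension", x$dim,
      "(", x$mE, "singles +", x$dim - x$mE, "duplexes )\n")
  invisible(x)
}

#' Locate a fixed point by Newton iteration
#'
#' @param sys an `ode_system`.
#' @param start starting state.
#' @param tol residual norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return list with `state`, `residual` (max-norm of the field) and
#'   `converged`.
#' @export
find_fixed_point <- function(sys, start, tol = 1e-13, max_iter = 50L) {
  x <- start
  for (i in seq_len(max_iter)) {
    fx <- sys$field(x)
    if (max(abs(fx)) < tol) break
    J <- sys$jacobian(x)
    step <- tryCatch(solve(J, fx), error = function(e) qr.solve(J, fx))
    x <- x - step
  }
  fx <- sys$field(x)
  list(state = x, residual = max(abs(fx)), converged = max(abs(fx)) < tol)
}

#' Fixed-point stability analysis
#'
#' Evaluates the Jacobian eigenvalues at a state and classifies it:
#' unstable if any eigenvalue has positive real part, degenerate if any
#' eigenvalue is (numerically) zero.
#'
#' @param sys an `ode_system`.
#' @param state state vector (a fixed-point candidate).
#' @param zero_tol magnitude below which an eigenvalue counts as zero.
#' @return list with `residual`, `eigenvalues`, `max_real`,
#'   `n_zero` and `classification` (`"unstable"`, `"stable"` or
#'   `"degenerate"`).
#' @export
fixed_point_stability <- function(sys, state, zero_tol = 1e-8) {
  ev <- eigen(sys$jacobian(state), only.values = TRUE)$values
  n_zero <- sum(Mod(ev) < zero_tol)
  max_real <- max(Re(ev))
  classification <- if (n_zero > 0L) "degenerate"
    else if (max_real > zero_tol) "unstable" else "stable"
  list(residual = max(abs(sys$field(state))), eigenvalues = ev,
       max_real = max_real, n_zero = n_zero,
       classification = classification)
}

#' Stability check at the high-fidelity single-molecule state
#'
#' For a singleton high-fidelity set R = \{x\}, the state with `[x] = 1` and
#' every other concentration 0 annihilates every pair propensity, so it is a
#' fixed point of the mean-field system. This helper locates that fixed
#' point by Newton iteration from a nearby perturbed state, verifies the
#' residual, and reports the Jacobian spectrum (expected: no zero
#' eigenvalue, at least one positive eigenvalue, hence unstable — the
#' replicating network is a growth process).
#'
#' @param sys an `ode_system` whose landscape has a singleton R.
#' @param delta size of the starting perturbation.
#' @return list with the Newton `fixed_point` result, the
#'   `high_fidelity_concentration` at the located fixed point, and the
#'   [fixed_point_stability()] report.
#' @export
mean_field_fixed_point_check <- function(sys, delta = 0.05) {
  R <- sys$ls$R
  if (R$size != 1L) stop("the fixed-point check requires a singleton R")
  xstar <- R$codes[1L] + 1L
  start <- numeric(sys$dim)
  start[xstar] <- 1 + delta
  fp <- find_fixed_point(sys, start)
  stab <- fixed_point_stability(sys, fp$state)
  list(fixed_point = fp,
       high_fidelity_concentration = fp$state[xstar],
       stability = stab)
}

#' Integrate the mean-field system
#'
#' @param sys an `ode_system`.
#' @param state0 initial state.
#' @param times output time grid.
#' @return `deSolve` output matrix (time in column 1).
#' @export
integrate_mean_field <- function(sys, state0, times) {
  deSolve::ode(y = state0, times = times,
               func = function(t, y, parms) list(sys$field(y)),
               parms = NULL, method = "lsoda")
}
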