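# Experiment protocols: initialization, replicative-mass calibration,
# parameter sweeps over (n, curvature, decay, clay) and the summary
# functionals g(theta) (finite-hit count) and f(theta) (mean hitting time).

#' Random initial population
#'
#' Draws `I` single-stranded molecules iid uniformly over sequence space,
#' optionally excluding the high-fidelity set (so the search must discover R
#' rather than start on it). Duplicates are allowed.
#'
#' @param n sequence length.
#' @param I initial population size `>= 1`.
#' @param R high-fidelity set to avoid (required when `avoid_R = TRUE`).
#' @param avoid_R if `TRUE`, resample any draw landing in R.
#' @return an `rna_population` of `I` single strands.
#' @export
init_population <- function(n, I, R = NULL, avoid_R = FALSE) {
  if (I < 1) stop("I must be >= 1")
  mE <- 4^n
  excl <- integer(0)
  if (avoid_R) {
    if (is.null(R)) stop("avoid_R requires a high-fidelity set R")
    excl <- manifold_codes(R, n)
    if (length(excl) >= mE) stop("cannot avoid R: it covers all of E")
  }
  codes <- sample.int(mE, I, replace = TRUE) - 1L
  while (length(excl) && any(codes %in% excl)) {
    bad <- codes %in% excl
    codes[bad] <- sample.int(mE, sum(bad), replace = TRUE) - 1L
  }
  population(singles = codes, n = n)
}

#' Calibrate the replication scale to a target replicative mass
#'
#' Sets the scale `a` of `k_rep = a f(x) s(x,y)` so that the initial total
#' RNA polymerization rate equals `target` exactly:
#' `a = target / sum f(x) s(x,y) N(x) (N(y) - I(x=y))`.
#'
#' @param pop initial `rna_population`.
#' @param ls an `rna_landscape` (its `a` is ignored).
#' @param target desired initial replicative mass, `> 0`.
#' @return the calibrated scale `a`.
#' @export
calibrate_replication_scale <- function(pop, ls, target) {
  if (target <= 0) stop("target replicative mass must be > 0")
  Ns <- pop$Ns
  w <- as.vector(ls$Sm %*% Ns)
  unscaled <- sum(ls$Fv * Ns * (w - ls$sdiag))
  if (unscaled <= 0)
    stop("unscaled replicative mass is zero (e.g. a single molecule); cannot calibrate")
  target / unscaled
}

#' Finite-hit count and mean hitting time
#'
#' For a multiset of hitting times with censored entries coded as `NA` (or
#' `Inf`): `g` is the number of finite times and `f` their mean, defined as
#' 0 when no hit occurred.
#'
#' @param tau numeric vector of hitting times; `NA`/`Inf` mean censored.
#' @return list with `g` (count) and `f` (mean, 0 if `g = 0`).
#' @export
summarize_hits <- function(tau) {
  finite <- tau[!is.na(tau) & is.finite(tau)]
  list(g = length(finite), f = if (length(finite)) mean(finite) else 0)
}

sweep_run <- function(ls, pop, rates, budget, v, seed) {
  tr <- simulate_population(ls, pop, rates, budget = budget, v = v,
                            stop_at = "tau_v", seed = seed)
  list(tau = tr$hits$tau_v, censor_time = tr$end_time,
       n_events = tr$n_events)
}

#' Core-model parameter sweep
#'
#' The baseline hitting-time experiment: sequence dimensions `n_values`
#' crossed with tent curvatures `k = l = -log(i)/n` over the terminus grid
#' `termini`, fidelity curvature `m = -log(0.25)/n`, `kss = kds = 1`, no
#' decay or clay. Per dimension, one random singleton R and one random
#' initial population of size `I` (disjoint from R) are drawn and re-used
#' across all curvature cells; the replication scale is calibrated per cell
#' so the initial replicative mass is `target_mass`. Each cell is replicated
#' `M` times with budget `budget`, recording tau_v (volume fraction `v`)
#' right-censored at budget exhaustion.
#'
#' @param seed base seed; all draws (R, X0, trajectories) derive from it.
#' @param n_values sequence dimensions.
#' @param termini terminus grid `i` defining curvatures `-log(i)/n`.
#' @param M replicates per parameter vector.
#' @param budget reaction budget per run.
#' @param v hitting volume fraction.
#' @param I initial population size.
#' @param target_mass initial replicative mass.
#' @return data frame of class `sweep_dataset`: one row per run with the
#'   parameter vector, `tau` (`NA` when censored), `censored` and
#'   `censor_time`; non-censored rows come first within each cell.
#' @export
run_core_sweep <- function(seed = 1L, n_values = c(3L, 4L),
                           termini = c(0.1, 0.05, 0.01, 0.005, 0.001),
                           M = 10L, budget = 5000L, v = 0.1, I = 10L,
                           target_mass = 10) {
  rates <- reaction_rates(kds = 1, kss = 1)
  rows <- list()
  run_seed <- as.integer(seed)
  for (n in n_values) {
    set.seed(seed + 10000L * n)
    R <- build_manifold(n = n, q = 0)
    pop <- init_population(n, I, R, avoid_R = TRUE)
    for (term in termini) {
      k <- curvature_from_terminus(term, n)
      ls <- landscape(R, form = "tent", k = k, l = k, a = 1)
      ls$a <- calibrate_replication_scale(pop, ls, target_mass)
      for (rep_i in seq_len(M)) {
        run_seed <- run_seed + 1L
        res <- sweep_run(ls, pop, rates, budget, v, run_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, terminus = term, k = k,
          replicate = rep_i, seed = run_seed,
          tau = if (is.na(res$tau)) NA_real_ else res$tau,
          censored = is.na(res$tau),
          censor_time = if (is.na(res$tau)) res$censor_time else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n, out$terminus, out$censored, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_dataset", "data.frame")
  out
}

#' Expanded (clay and decay) parameter sweep
#'
#' Extends the core sweep with decay rate `kdecay ~ U(0,1)`, clay fraction
#' `fclay ~ U(0,1)` and clay fidelity `p ~ U(0,1)`: for each of the
#' `(n, terminus)` grid cells, `draws_per_cell` iid draws of the continuous
#' triple are taken (a product design with uniform marginals). Per parameter
#' vector a fresh singleton R and initial population disjoint from R are
#' drawn; the replicative mass is split between RNA and clay polymerization:
#' initial RNA mass `(1 - fclay) * total_mass` and clay mass
#' `fclay * total_mass` (so `kclay_p = fclay * total_mass / I`);
#' `kss = kds = kclay_o = 1`.
#'
#' @inheritParams run_core_sweep
#' @param draws_per_cell number of continuous-parameter draws per grid cell.
#' @param total_mass combined initial polymerization mass split by `fclay`.
#' @return `sweep_dataset` data frame, one row per run, with columns
#'   `n, terminus, k, kdecay, fclay, p_clay, replicate, seed, tau, censored,
#'   censor_time`.
#' @export
run_expanded_sweep <- function(seed = 1L, n_values = c(3L, 4L),
                               termini = c(0.1, 0.05, 0.01, 0.005, 0.001),
                               draws_per_cell = 24L, M = 10L,
                               budget = 5000L, v = 0.1, I = 10L,
                               total_mass = 20) {
  rows <- list()
  run_seed <- as.integer(seed) + 500000L
  cell <- 0L
  for (n in n_values) for (term in termini) {
    k <- curvature_from_terminus(term, n)
    for (d in seq_len(draws_per_cell)) {
      cell <- cell + 1L
      set.seed(seed + 20000L + cell)
      kdecay <- stats::runif(1L)
      fclay <- stats::runif(1L)
      p_clay <- stats::runif(1L)
      R <- build_manifold(n = n, q = 0)
      pop <- init_population(n, I, R, avoid_R = TRUE)
      ls <- landscape(R, form = "tent", k = k, l = k, a = 1)
      ls$a <- calibrate_replication_scale(pop, ls, (1 - fclay) * total_mass)
      rates <- reaction_rates(kds = 1, kss = 1, kdecay = kdecay,
                              kclay_o = 1,
                              kclay_p = fclay * total_mass / I,
                              p_clay = max(p_clay, 1e-12))
      for (rep_i in seq_len(M)) {
        run_seed <- run_seed + 1L
        res <- sweep_run(ls, pop, rates, budget, v, run_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, terminus = term, k = k, kdecay = kdecay, fclay = fclay,
          p_clay = p_clay, replicate = rep_i, seed = run_seed,
          tau = if (is.na(res$tau)) NA_real_ else res$tau,
          censored = is.na(res$tau),
          censor_time = if (is.na(res$tau)) res$censor_time else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_dataset", "data.frame")
  out
}

#' Per-cell summary of a sweep dataset
#'
#' @param sweep a `sweep_dataset`.
#' @return data frame with one row per parameter vector and columns `g`
#'   (finite hits) and `f` (mean finite hitting time, 0 if none).
#' @export
sweep_summary <- function(sweep) {
  theta_cols <- intersect(c("n", "terminus", "k", "kdecay", "fclay", "p_clay"),
                          names(sweep))
  key <- interaction(sweep[theta_cols], drop = TRUE)
  out <- do.call(rbind, lapply(split(sweep, key), function(d) {
    s <- summarize_hits(d$tau)
    cbind(d[1L, theta_cols, drop = FALSE], g = s$g, f = s$f)
  }))
  rownames(out) <- NULL
  out
}
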