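# Exact Gillespie simulation of the reaction network: duplex formation and
# dissociation, template-directed RNA polymerization, decay, clay
# oligomerization/polymerization. Counts are dense over 4^n codes; the
# similarity row-sum w = S N is maintained incrementally so each event costs
# O(4^n) vector work.

#' Reaction rate constants
#'
#' @param kds double-strand formation rate.
#' @param kss double-strand dissociation rate.
#' @param kdecay single-strand decay rate (duplexes are assumed stable).
#' @param kclay_o clay oligomerization rate (zero order; emits a uniformly
#'   random sequence).
#' @param kclay_p clay polymerization rate per single-strand molecule.
#' @param p_clay clay per-site copying fidelity in `(0, 1]`.
#' @param kmic vesiculation rate per single-strand molecule (used by the
#'   compartmentalized simulator).
#' @return list of class `reaction_rates`.
#' @export
reaction_rates <- function(kds = 1, kss = 1, kdecay = 0, kclay_o = 0,
                           kclay_p = 0, p_clay = 0.9, kmic = 0) {
  vals <- c(kds = kds, kss = kss, kdecay = kdecay, kclay_o = kclay_o,
            kclay_p = kclay_p, kmic = kmic)
  if (any(vals < 0)) stop("rate constants must be >= 0")
  if (p_clay <= 0 || p_clay > 1) stop("p_clay must lie in (0, 1]")
  structure(list(kds = kds, kss = kss, kdecay = kdecay, kclay_o = kclay_o,
                 kclay_p = kclay_p, p_clay = p_clay, kmic = kmic),
            class = "reaction_rates")
}

#' Per-channel reaction rates of a population
#'
#' Evaluates the propensity of every reaction channel on the current state,
#' restricted to the nonzero support:
#' ds formation `0.5 * sum kds N(x) N(xc)`, dissociation `kss * N(X2)`,
#' polymerization `sum a f(x) s(x,y) N(x)(N(y) - I(x=y))` over ordered pairs,
#' decay `kdecay * N(X1)`, clay oligomerization `kclay_o`, clay
#' polymerization `kclay_p * N(X1)` (molecule counts).
#'
#' @param pop an `rna_population`.
#' @param ls an `rna_landscape`.
#' @param rates a `reaction_rates` object.
#' @return named numeric vector with channels `ds_form`, `ds_dissoc`,
#'   `rna_poly`, `decay`, `clay_oligo`, `clay_poly` and their sum `total`.
#' @export
channel_rates <- function(pop, ls, rates) {
  stopifnot(inherits(pop, "rna_population"))
  if (any(pop$Ns < 0L) || any(pop$Nd < 0L)) stop("negative counts: invariant failure")
  Ns <- pop$Ns
  w <- as.vector(ls$Sm %*% Ns)
  rowmass <- ls$Fv * Ns * (w - ls$sdiag)
  Stot <- sum(Ns)
  out <- c(
    ds_form   = 0.5 * rates$kds * sum(Ns * Ns[ls$comp + 1L]),
    ds_dissoc = rates$kss * sum(pop$Nd),
    rna_poly  = ls$a * sum(rowmass),
    decay     = rates$kdecay * Stot,
    clay_oligo = if (Stot + sum(pop$Nd) >= 0) rates$kclay_o else 0,
    clay_poly = rates$kclay_p * Stot
  )
  c(out, total = sum(out))
}

#' Naive full-space channel rates (test oracle)
#'
#' Recomputes every channel total by explicit summation over all `4^n`
#' species and all `16^n` ordered pairs, with no support restriction.
#' Intended as an independent oracle for small `n`.
#'
#' @inheritParams channel_rates
#' @return named numeric vector as in [channel_rates()].
#' @export
channel_rates_naive <- function(pop, ls, rates) {
  n <- pop$n
  mE <- 4^n
  ds <- 0; rep_tot <- 0
  for (x in 0:(mE - 1L)) {
    xc <- complement_code(x, n)
    ds <- ds + rates$kds * pop$Ns[x + 1L] * pop$Ns[xc + 1L]
    for (y in 0:(mE - 1L)) {
      krep <- ls$a * ls$Fv[x + 1L] * ls$Sm[x + 1L, y + 1L]
      rep_tot <- rep_tot + krep * pop$Ns[x + 1L] * (pop$Ns[y + 1L] - (x == y))
    }
  }
  out <- c(ds_form = 0.5 * ds,
           ds_dissoc = rates$kss * sum(pop$Nd),
           rna_poly = rep_tot,
           decay = rates$kdecay * sum(pop$Ns),
           clay_oligo = rates$kclay_o,
           clay_poly = rates$kclay_p * sum(pop$Ns))
  c(out, total = sum(out))
}

#' One exact SSA step
#'
#' Draws the waiting time `dt ~ Exponential(rate = total)` and one reaction
#' event (channel proportional to its propensity, reactants within channel
#' proportional to their contributions), and returns the updated population.
#'
#' @inheritParams channel_rates
#' @return list with `dt`, `event` (list: `channel`, reactant/product codes)
#'   and `pop` (new state); or `NULL` if the total rate is zero (absorbing
#'   state).
#' @export
ssa_step <- function(pop, ls, rates) {
  cr <- channel_rates(pop, ls, rates)
  if (cr[["total"]] <= 0) return(NULL)
  dt <- stats::rexp(1L, rate = cr[["total"]])
  ev <- draw_event(pop$Ns, pop$Nd, ls, rates, cr)
  pop2 <- apply_event(pop, ev, ls)
  list(dt = dt, event = ev, pop = pop2)
}

# choose the channel and reactants; returns list(channel, r1, r2, prod)
draw_event <- function(Ns, Nd, ls, rates, cr) {
  n <- ls$n
  mE <- 4^n
  channels <- c("ds_form", "ds_dissoc", "rna_poly", "decay", "clay_oligo", "clay_poly")
  ch <- channels[sample.int(6L, 1L, prob = pmax(cr[channels], 0))]
  r1 <- r2 <- prod <- NA_integer_
  switch(ch,
    ds_form = {
      wds <- Ns * Ns[ls$comp + 1L]
      r1 <- sample.int(mE, 1L, prob = wds) - 1L
      r2 <- complement_code(r1, n)
      prod <- min(r1, r2)
    },
    ds_dissoc = {
      r1 <- sample.int(mE, 1L, prob = Nd) - 1L
      prod <- r1                     # dissociates into prod and its complement
    },
    rna_poly = {
      w <- as.vector(ls$Sm %*% Ns)
      rowmass <- ls$Fv * Ns * (w - ls$sdiag)
      r1 <- sample.int(mE, 1L, prob = pmax(rowmass, 0)) - 1L   # polymerase
      yw <- ls$Sm[r1 + 1L, ] * Ns
      yw[r1 + 1L] <- yw[r1 + 1L] - ls$sdiag[r1 + 1L]
      r2 <- sample.int(mE, 1L, prob = pmax(yw, 0)) - 1L        # template
      prod <- sample_offspring_code(ls$Pv[r1 + 1L], r2, n)
    },
    decay = {
      r1 <- sample.int(mE, 1L, prob = Ns) - 1L
    },
    clay_oligo = {
      prod <- sample.int(mE, 1L) - 1L
    },
    clay_poly = {
      r1 <- sample.int(mE, 1L, prob = Ns) - 1L                 # template
      prod <- sample_offspring_code(rates$p_clay, r1, n)
    })
  list(channel = ch, r1 = r1, r2 = r2, prod = prod)
}

# apply an event record to an rna_population
apply_event <- function(pop, ev, ls) {
  n <- pop$n
  switch(ev$channel,
    ds_form = {
      pop$Ns[ev$r1 + 1L] <- pop$Ns[ev$r1 + 1L] - 1L
      pop$Ns[ev$r2 + 1L] <- pop$Ns[ev$r2 + 1L] - 1L
      pop$Nd[ev$prod + 1L] <- pop$Nd[ev$prod + 1L] + 1L
      pop$K <- pop$K - 1L
    },
    ds_dissoc = {
      pop$Nd[ev$r1 + 1L] <- pop$Nd[ev$r1 + 1L] - 1L
      pop$Ns[ev$prod + 1L] <- pop$Ns[ev$prod + 1L] + 1L
      xc <- complement_code(ev$prod, n)
      pop$Ns[xc + 1L] <- pop$Ns[xc + 1L] + 1L
      pop$K <- pop$K + 1L
    },
    decay = {
      pop$Ns[ev$r1 + 1L] <- pop$Ns[ev$r1 + 1L] - 1L
      pop$K <- pop$K - 1L
    },
    {
      # rna_poly, clay_oligo, clay_poly all add one single strand
      pop$Ns[ev$prod + 1L] <- pop$Ns[ev$prod + 1L] + 1L
      pop$K <- pop$K + 1L
    })
  if (any(pop$Ns < 0L) || any(pop$Nd < 0L)) stop("negative counts: invariant failure")
  pop
}

#' Simulate a replicating RNA population
#'
#' Runs the exact SSA on the full reaction network until the reaction budget
#' is exhausted, the registered hitting condition fires, or the state becomes
#' absorbing (zero total rate). Hitting times tau_rep (first growth beyond
#' the initial size), tau_R (first appearance of a high-fidelity sequence,
#' free or in a duplex), tau_min (attainment of the running minimum of the
#' volume fraction after tau_R) and tau_v (volume fraction reaching `v`) are
#' detected online.
#'
#' @param ls an `rna_landscape` (carries the high-fidelity set and the
#'   replication scale `a`).
#' @param init initial `rna_population`.
#' @param rates a `reaction_rates` object.
#' @param budget maximum number of reactions `N >= 0`.
#' @param v target volume fraction for tau_v, in `(0, 1]`, or `NULL` to
#'   disable tau_v detection.
#' @param stop_at stop the run when this hitting event fires: one of
#'   `"tau_v"`, `"tau_R"`, `"tau_rep"` or `"none"` (run out the budget).
#' @param record_mu record the polymerization image measure aggregated on
#'   the manifold partition every `mu_every` events.
#' @param mu_every recording stride for the image measure.
#' @param seed optional integer seed for reproducibility.
#' @param tau_min_first if `TRUE`, tau_min is the first attainment of the
#'   running minimum of V after tau_R; default is the last attainment.
#' @return object of class `rna_trajectory`: the event log, time series of
#'   `K`, volume fraction `V` and molecule counts per manifold class, the
#'   hitting records, optionally the image-measure series, and the final
#'   population.
#' @examples
#' R <- build_manifold(members = "AAA")
#' ls <- landscape(R, k = 1.5, l = 1.5, a = 10)
#' pop <- population(c("AAG", "AAG", "UUC"))
#' tr <- simulate_population(ls, pop, reaction_rates(), budget = 50, v = 0.5,
#'                           seed = 1)
#' @export
simulate_population <- function(ls, init, rates = reaction_rates(),
                                budget = 1000L, v = NULL,
                                stop_at = if (is.null(v)) "none" else "tau_v",
                                record_mu = FALSE, mu_every = 10L,
                                seed = NULL, tau_min_first = FALSE) {
  stopifnot(inherits(ls, "rna_landscape"), inherits(init, "rna_population"))
  if (init$n != ls$n) stop("population and landscape dimensions differ")
  if (budget < 0) stop("reaction budget must be >= 0")
  stop_at <- match.arg(stop_at, c("tau_v", "tau_R", "tau_rep", "none"))
  if (!is.null(seed)) set.seed(seed)
  n <- ls$n
  mE <- 4^n
  comp <- ls$comp
  cls <- ls$class
  in_R <- ls$in_R
  dupR <- in_R | in_R[comp + 1L]

  Ns <- init$Ns
  Nd <- init$Nd
  K <- init$K
  I <- K
  w <- as.vector(ls$Sm %*% Ns)          # similarity row-sums, kept incrementally
  Stot <- sum(Ns)
  Dtot <- sum(Nd)
  nXR <- sum(Ns[in_R]) + sum(Nd[dupR])
  ccnt <- as.integer(rowsum_counts(Ns, cls, n) + rowsum_counts(Nd, cls, n))

  t_now <- 0
  Vnow <- if (K > 0) nXR / K else NA_real_
  hits <- list(tau_rep = NA_real_, tau_R = NA_real_,
               tau_min = NA_real_, tau_v = NA_real_)
  if (nXR >= 1L && is.na(hits$tau_R)) hits$tau_R <- 0
  vmin <- if (!is.na(hits$tau_R)) Vnow else NA_real_
  if (!is.na(hits$tau_R)) hits$tau_min <- 0
  if (!is.null(v) && !is.na(Vnow) && Vnow >= v) hits$tau_v <- 0

  nb <- as.integer(budget)
  ev_time <- numeric(nb); ev_ch <- character(nb)
  ev_r1 <- ev_r2 <- ev_prod <- integer(nb)
  ev_K <- integer(nb); ev_V <- numeric(nb)
  cls_series <- matrix(0L, nb + 1L, n + 1L,
                       dimnames = list(NULL, paste0("H", 0:n)))
  cls_series[1L, ] <- ccnt
  mu_list <- list(); mu_times <- numeric(0)

  stopped <- "budget"
  nev <- 0L
  hit_fired <- function() {
    stop_at != "none" && !is.na(hits[[stop_at]])
  }

  while (nev < nb && !hit_fired()) {
    # --- channel totals (O(4^n) vector work) ---
    wds <- Ns * Ns[comp + 1L]
    ds_tot <- 0.5 * rates$kds * sum(wds)
    ss_tot <- rates$kss * Dtot
    rowmass <- ls$Fv * Ns * (w - ls$sdiag)
    rep_tot <- ls$a * sum(rowmass)
    dec_tot <- rates$kdecay * Stot
    co_tot <- rates$kclay_o
    cp_tot <- rates$kclay_p * Stot
    total <- ds_tot + ss_tot + rep_tot + dec_tot + co_tot + cp_tot
    if (total <= 0) { stopped <- "absorbed"; break }
    t_now <- t_now + stats::rexp(1L, rate = total)

    u <- stats::runif(1L) * total
    r1 <- r2 <- prod <- NA_integer_
    if (u < ds_tot) {
      ch <- "ds_form"
      r1 <- sample.int(mE, 1L, prob = wds) - 1L
      r2 <- comp[r1 + 1L]
      prod <- min(r1, r2)
      Ns[r1 + 1L] <- Ns[r1 + 1L] - 1L; Ns[r2 + 1L] <- Ns[r2 + 1L] - 1L
      Nd[prod + 1L] <- Nd[prod + 1L] + 1L
      w <- w - ls$Sm[, r1 + 1L] - ls$Sm[, r2 + 1L]
      Stot <- Stot - 2L; Dtot <- Dtot + 1L; K <- K - 1L
      nXR <- nXR - in_R[r1 + 1L] - in_R[r2 + 1L] + dupR[prod + 1L]
      ccnt[cls[r1 + 1L] + 1L] <- ccnt[cls[r1 + 1L] + 1L] - 1L
      # duplex has the class of its strands (partition is complement-invariant)
    } else if (u < ds_tot + ss_tot) {
      ch <- "ds_dissoc"
      r1 <- sample.int(mE, 1L, prob = Nd) - 1L
      prod <- r1
      xc <- comp[r1 + 1L]
      Nd[r1 + 1L] <- Nd[r1 + 1L] - 1L
      Ns[r1 + 1L] <- Ns[r1 + 1L] + 1L; Ns[xc + 1L] <- Ns[xc + 1L] + 1L
      w <- w + ls$Sm[, r1 + 1L] + ls$Sm[, xc + 1L]
      Stot <- Stot + 2L; Dtot <- Dtot - 1L; K <- K + 1L
      nXR <- nXR - dupR[r1 + 1L] + in_R[r1 + 1L] + in_R[xc + 1L]
      ccnt[cls[r1 + 1L] + 1L] <- ccnt[cls[r1 + 1L] + 1L] + 1L
    } else if (u < ds_tot + ss_tot + rep_tot) {
      ch <- "rna_poly"
      r1 <- sample.int(mE, 1L, prob = pmax(rowmass, 0)) - 1L
      yw <- ls$Sm[r1 + 1L, ] * Ns
      yw[r1 + 1L] <- yw[r1 + 1L] - ls$sdiag[r1 + 1L]
      r2 <- sample.int(mE, 1L, prob = pmax(yw, 0)) - 1L
      prod <- sample_offspring_code(ls$Pv[r1 + 1L], r2, n)
      Ns[prod + 1L] <- Ns[prod + 1L] + 1L
      w <- w + ls$Sm[, prod + 1L]
      Stot <- Stot + 1L; K <- K + 1L
      nXR <- nXR + in_R[prod + 1L]
      ccnt[cls[prod + 1L] + 1L] <- ccnt[cls[prod + 1L] + 1L] + 1L
    } else if (u < ds_tot + ss_tot + rep_tot + dec_tot) {
      ch <- "decay"
      r1 <- sample.int(mE, 1L, prob = Ns) - 1L
      Ns[r1 + 1L] <- Ns[r1 + 1L] - 1L
      w <- w - ls$Sm[, r1 + 1L]
      Stot <- Stot - 1L; K <- K - 1L
      nXR <- nXR - in_R[r1 + 1L]
      ccnt[cls[r1 + 1L] + 1L] <- ccnt[cls[r1 + 1L] + 1L] - 1L
    } else if (u < ds_tot + ss_tot + rep_tot + dec_tot + co_tot) {
      ch <- "clay_oligo"
      prod <- sample.int(mE, 1L) - 1L
      Ns[prod + 1L] <- Ns[prod + 1L] + 1L
      w <- w + ls$Sm[, prod + 1L]
      Stot <- Stot + 1L; K <- K + 1L
      nXR <- nXR + in_R[prod + 1L]
      ccnt[cls[prod + 1L] + 1L] <- ccnt[cls[prod + 1L] + 1L] + 1L
    } else {
      ch <- "clay_poly"
      r1 <- sample.int(mE, 1L, prob = Ns) - 1L
      prod <- sample_offspring_code(rates$p_clay, r1, n)
      Ns[prod + 1L] <- Ns[prod + 1L] + 1L
      w <- w + ls$Sm[, prod + 1L]
      Stot <- Stot + 1L; K <- K + 1L
      nXR <- nXR + in_R[prod + 1L]
      ccnt[cls[prod + 1L] + 1L] <- ccnt[cls[prod + 1L] + 1L] + 1L
    }

    nev <- nev + 1L
    Vnow <- if (K > 0) nXR / K else NA_real_
    ev_time[nev] <- t_now; ev_ch[nev] <- ch
    ev_r1[nev] <- r1; ev_r2[nev] <- r2; ev_prod[nev] <- prod
    ev_K[nev] <- K; ev_V[nev] <- Vnow
    cls_series[nev + 1L, ] <- ccnt

    # --- online hitting detection ---
    if (is.na(hits$tau_rep) && K > I) hits$tau_rep <- t_now
    if (is.na(hits$tau_R) && nXR >= 1L) {
      hits$tau_R <- t_now
      vmin <- Vnow
      hits$tau_min <- t_now
    } else if (!is.na(hits$tau_R) && !is.na(Vnow)) {
      if (Vnow < vmin || (!tau_min_first && Vnow == vmin)) {
        vmin <- Vnow
        hits$tau_min <- t_now
      }
    }
    if (!is.null(v) && is.na(hits$tau_v) && !is.na(Vnow) && Vnow >= v)
      hits$tau_v <- t_now

    if (record_mu && (nev %% mu_every == 0L || hit_fired() || nev == nb)) {
      snap <- structure(list(n = n, Ns = Ns, Nd = Nd, K = K),
                        class = "rna_population")
      mu <- tryCatch(image_measure(domain_measure(snap, ls), ls),
                     rnahit_undefined_measure = function(e) NULL)
      if (!is.null(mu)) {
        mu_list[[length(mu_list) + 1L]] <- mu$class_mass
        mu_times <- c(mu_times, t_now)
      }
    }
  }
  if (hit_fired()) stopped <- "hit"

  events <- data.frame(time = ev_time[seq_len(nev)], channel = ev_ch[seq_len(nev)],
                       r1 = ev_r1[seq_len(nev)], r2 = ev_r2[seq_len(nev)],
                       prod = ev_prod[seq_len(nev)], K = ev_K[seq_len(nev)],
                       V = ev_V[seq_len(nev)], stringsAsFactors = FALSE)
  final <- structure(list(n = n, Ns = Ns, Nd = Nd, K = K),
                     class = "rna_population")
  structure(list(
    n = n, I = I, budget = nb, n_events = nev, end_time = t_now,
    stopped = stopped, v = v, R = ls$R$codes, seed = seed,
    events = events,
    class_counts = cls_series[seq_len(nev + 1L), , drop = FALSE],
    mu = if (length(mu_list)) do.call(rbind, mu_list) else NULL,
    mu_times = mu_times,
    hits = hits, init = init, final = final,
    tau_min_first = tau_min_first
  ), class = "rna_trajectory")
}

# molecule counts aggregated by manifold class (0..n)
rowsum_counts <- function(counts, cls, n) {
  out <- numeric(n + 1L)
  agg <- rowsum(as.numeric(counts), cls)
  out[as.integer(rownames(agg)) + 1L] <- agg
  out
}

#' @export
print.rna_trajectory <- function(x, ...) {
  cat("SSA trajectory: n =", x$n, ", I =", x$I, ",", x$n_events,
      "events in", format(x$end_time, digits = 4), "time units (",
      x$stopped, ")\n")
  fh <- Filter(Negate(is.na), x$hits)
  if (length(fh))
    cat("  hits:", paste(names(fh), signif(unlist(fh), 4), sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}
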