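# Compartmentalized simulation: molecules carry positions on [-T, T]; vesicle
# intervals (nested or disjoint, never crossing) restrict which
# polymerase-template pairs can react. Molecule-level representation, meant
# for small populations; the count-based simulator covers the well-mixed case.

# innermost vesicle region containing each position (0 = outside all vesicles)
region_of <- function(pos, vesicles) {
  if (is.null(vesicles) || nrow(vesicles) == 0L) return(rep.int(0L, length(pos)))
  vapply(pos, function(p) {
    inside <- which(vesicles[, 1L] <= p & p <= vesicles[, 2L])
    if (length(inside) == 0L) return(0L)
    inside[which.min(vesicles[inside, 2L] - vesicles[inside, 1L])]
  }, integer(1))
}

# would [lo, hi] cross (partially overlap) any existing interval?
crosses_existing <- function(lo, hi, vesicles) {
  if (is.null(vesicles) || nrow(vesicles) == 0L) return(FALSE)
  any(vesicles[, 1L] < hi & lo < vesicles[, 2L] &          # overlap
        !(vesicles[, 1L] <= lo & hi <= vesicles[, 2L]) &   # not nested inside
        !(lo <= vesicles[, 1L] & vesicles[, 2L] <= hi))    # not enclosing
}

# replicative mass restricted to pairs sharing an innermost region;
# returns list(total, per-polymerase masses, region ids)
restricted_rep_mass <- function(codes, regions, ls) {
  total <- 0
  polymass <- numeric(length(codes))
  for (r in unique(regions)) {
    v <- which(regions == r)
    if (length(v) < 2L) next
    Sv <- ls$Sm[codes[v] + 1L, codes[v] + 1L, drop = FALSE]
    Fv <- ls$Fv[codes[v] + 1L]
    rowm <- Fv * (rowSums(Sv) - diag(Sv))
    polymass[v] <- ls$a * rowm
    total <- total + ls$a * sum(rowm)
  }
  list(total = total, polymass = polymass)
}

#' Simulate a compartmentalized RNA population
#'
#' Molecule-level SSA with 1-D positions on `[-T, T]` and vesiculation:
#' a vesiculation event (rate `kmic` per single strand) forms an interval of
#' width `vesicle_width` centred at a random single-strand molecule, rejected
#' as a no-op if it would cross an existing interval (vesicles nest or are
#' disjoint). Replication is restricted to polymerase-template pairs whose
#' positions share the same innermost vesicle region, so the total
#' replicative mass never exceeds the unrestricted (well-mixed) value.
#' Offspring inherit the template's position; initial molecules are placed
#' uniformly.
#'
#' @param ls an `rna_landscape`.
#' @param init initial `rna_population` (positions drawn uniformly), or a
#'   data frame with columns `code` and `pos` for explicit placement.
#' @param rates a `reaction_rates` object (`kmic` drives vesiculation).
#' @param budget maximum number of reactions.
#' @param T_domain half-width of the spatial domain.
#' @param vesicle_width width of newly formed vesicle intervals.
#' @param seed optional integer seed.
#' @return object of class `rna_trajectory_spatial`: event log, the series
#'   of restricted and unrestricted replicative mass, vesicle intervals, and
#'   the final molecule table.
#' @export
simulate_compartments <- function(ls, init, rates = reaction_rates(kmic = 0.5),
                                  budget = 200L, T_domain = 1,
                                  vesicle_width = 0.25, seed = NULL) {
  stopifnot(inherits(ls, "rna_landscape"))
  if (!is.null(seed)) set.seed(seed)
  n <- ls$n
  if (is.data.frame(init)) {
    codes <- as.integer(init$code); pos <- as.numeric(init$pos)
    check_codes(codes, n)
  } else {
    stopifnot(inherits(init, "rna_population"))
    codes <- rep.int(which(init$Ns > 0L) - 1L, init$Ns[init$Ns > 0L])
    pos <- stats::runif(length(codes), -T_domain, T_domain)
    if (sum(init$Nd) > 0L) stop("compartmentalized runs start from single strands")
  }
  type <- rep.int(1L, length(codes))     # 1 = single, 2 = duplex (canonical code)
  vesicles <- matrix(numeric(0), 0L, 2L)
  t_now <- 0
  nb <- as.integer(budget)
  ev_time <- numeric(nb); ev_ch <- character(nb)
  rm_restricted <- numeric(nb + 1L); rm_unrestricted <- numeric(nb + 1L)
  n_vesicles <- integer(nb + 1L)

  mass_snapshot <- function() {
    singles <- which(type == 1L)
    regions <- region_of(pos[singles], vesicles)
    res <- restricted_rep_mass(codes[singles], regions, ls)
    unres <- restricted_rep_mass(codes[singles],
                                 rep.int(0L, length(singles)), ls)
    list(singles = singles, regions = regions, res = res, unres = unres)
  }
  snap <- mass_snapshot()
  rm_restricted[1L] <- snap$res$total
  rm_unrestricted[1L] <- snap$unres$total
  n_vesicles[1L] <- 0L
  nev <- 0L
  stopped <- "budget"

  while (nev < nb) {
    singles <- which(type == 1L)
    duplexes <- which(type == 2L)
    nS <- length(singles)
    cnt <- tabulate(codes[singles] + 1L, nbins = 4^n)
    wds <- cnt * cnt[ls$comp + 1L]
    ds_tot <- 0.5 * rates$kds * sum(wds)
    ss_tot <- rates$kss * length(duplexes)
    regions <- region_of(pos[singles], vesicles)
    rep_res <- restricted_rep_mass(codes[singles], regions, ls)
    rep_tot <- rep_res$total
    dec_tot <- rates$kdecay * nS
    co_tot <- rates$kclay_o
    cp_tot <- rates$kclay_p * nS
    mic_tot <- rates$kmic * nS
    total <- ds_tot + ss_tot + rep_tot + dec_tot + co_tot + cp_tot + mic_tot
    if (total <= 0) { stopped <- "absorbed"; break }
    t_now <- t_now + stats::rexp(1L, rate = total)
    u <- stats::runif(1L) * total

    if (u < ds_tot) {
      ch <- "ds_form"
      x <- sample.int(4^n, 1L, prob = wds) - 1L
      xc <- ls$comp[x + 1L]
      i <- resample(singles[codes[singles] == x], 1L)
      j <- resample(setdiff(singles[codes[singles] == xc], i), 1L)
      codes[i] <- min(x, xc); type[i] <- 2L
      keep <- setdiff(seq_along(codes), j)
      codes <- codes[keep]; type <- type[keep]; pos <- pos[keep]
    } else if (u < ds_tot + ss_tot) {
      ch <- "ds_dissoc"
      i <- resample(duplexes, 1L)
      cc <- codes[i]
      type[i] <- 1L
      codes <- c(codes, ls$comp[cc + 1L]); type <- c(type, 1L)
      pos <- c(pos, pos[i])
    } else if (u < ds_tot + ss_tot + rep_tot) {
      ch <- "rna_poly"
      i <- singles[sample.int(nS, 1L, prob = pmax(rep_res$polymass, 0))]
      mates <- singles[regions == regions[match(i, singles)]]
      mates <- setdiff(mates, i)
      wy <- ls$Sm[codes[i] + 1L, codes[mates] + 1L]
      j <- mates[sample.int(length(mates), 1L, prob = pmax(wy, 0))]
      z <- sample_offspring_code(ls$Pv[codes[i] + 1L], codes[j], n)
      codes <- c(codes, z); type <- c(type, 1L); pos <- c(pos, pos[j])
    } else if (u < ds_tot + ss_tot + rep_tot + dec_tot) {
      ch <- "decay"
      i <- resample(singles, 1L)
      keep <- setdiff(seq_along(codes), i)
      codes <- codes[keep]; type <- type[keep]; pos <- pos[keep]
    } else if (u < ds_tot + ss_tot + rep_tot + dec_tot + co_tot) {
      ch <- "clay_oligo"
      codes <- c(codes, sample.int(4^n, 1L) - 1L); type <- c(type, 1L)
      pos <- c(pos, stats::runif(1L, -T_domain, T_domain))
    } else if (u < ds_tot + ss_tot + rep_tot + dec_tot + co_tot + cp_tot) {
      ch <- "clay_poly"
      i <- resample(singles, 1L)
      z <- sample_offspring_code(rates$p_clay, codes[i], n)
      codes <- c(codes, z); type <- c(type, 1L); pos <- c(pos, pos[i])
    } else {
      i <- resample(singles, 1L)
      lo <- max(-T_domain, pos[i] - vesicle_width / 2)
      hi <- min(T_domain, pos[i] + vesicle_width / 2)
      if (crosses_existing(lo, hi, vesicles)) {
        ch <- "vesiculate_rejected"
      } else {
        ch <- "vesiculate"
        vesicles <- rbind(vesicles, c(lo, hi))
      }
    }

    nev <- nev + 1L
    ev_time[nev] <- t_now; ev_ch[nev] <- ch
    snap_singles <- which(type == 1L)
    snap_regions <- region_of(pos[snap_singles], vesicles)
    rm_restricted[nev + 1L] <-
      restricted_rep_mass(codes[snap_singles], snap_regions, ls)$total
    rm_unrestricted[nev + 1L] <-
      restricted_rep_mass(codes[snap_singles],
                          rep.int(0L, length(snap_singles)), ls)$total
    n_vesicles[nev + 1L] <- nrow(vesicles)
  }

  structure(list(
    n = n, budget = nb, n_events = nev, end_time = t_now, stopped = stopped,
    events = data.frame(time = ev_time[seq_len(nev)],
                        channel = ev_ch[seq_len(nev)],
                        stringsAsFactors = FALSE),
    rep_mass_restricted = rm_restricted[seq_len(nev + 1L)],
    rep_mass_unrestricted = rm_unrestricted[seq_len(nev + 1L)],
    n_vesicles = n_vesicles[seq_len(nev + 1L)],
    vesicles = vesicles,
    molecules = data.frame(code = codes, type = type, pos = pos),
    seed = seed
  ), class = "rna_trajectory_spatial")
}

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

#' Replicative mass of a positioned molecule set
#'
#' Computes the total replication propensity
#' `a * sum f(x_i) s(x_i, x_j)` over ordered molecule pairs, both
#' unrestricted (well mixed) and restricted to pairs sharing the same
#' innermost vesicle region. The restricted value never exceeds the
#' unrestricted one, and is strictly smaller as soon as two molecules sit in
#' disjoint regions with a nonzero cross term.
#'
#' @param ls an `rna_landscape`.
#' @param molecules data frame with columns `code` (single-strand sequence
#'   codes) and `pos` (positions).
#' @param vesicles two-column matrix of vesicle intervals (lo, hi), nested
#'   or disjoint; `NULL` for none.
#' @return list with `restricted` and `unrestricted` totals.
#' @export
replicative_mass <- function(ls, molecules, vesicles = NULL) {
  codes <- as.integer(molecules$code)
  check_codes(codes, ls$n)
  regions <- region_of(molecules$pos, vesicles)
  list(restricted = restricted_rep_mass(codes, regions, ls)$total,
       unrestricted = restricted_rep_mass(codes, rep.int(0L, length(codes)),
                                          ls)$total)
}

#' @export
print.rna_trajectory_spatial <- function(x, ...) {
  cat("Compartmentalized SSA trajectory:", x$n_events, "events,",
      nrow(x$vesicles), "vesicles,", nrow(x$molecules), "molecules\n")
  invisible(x)
}
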