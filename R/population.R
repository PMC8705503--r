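# Population state: a counting measure over species (single strands and
# duplexes). Dense representation: counts indexed by sequence code, with
# duplex counts stored at the canonical code min(x, xc).

#' Construct a population state
#'
#' A population is the counting measure N_t over species: single strands
#' `{x}` and duplexes `{x, xc}` (canonicalized at `min(code, comp(code))`).
#' Counts are dense integer vectors over all `4^n` codes.
#'
#' @param singles sequences present as single strands: character vector,
#'   integer codes, or a named count vector over codes (names = codes).
#'   Repeats denote multiple molecules.
#' @param duplexes sequences whose duplex `{x, xc}` is present; repeats
#'   denote multiple duplex molecules.
#' @param n sequence length (required for codes or an empty population).
#' @return object of class `rna_population` with fields `n`, `Ns` (single
#'   counts by code), `Nd` (duplex counts by canonical code) and `K` (total
#'   molecule count).
#' @examples
#' population(c("AAA", "AAA", "UUU"), duplexes = "AAG")
#' @export
population <- function(singles = NULL, duplexes = NULL, n = NULL) {
  to_codes <- function(x) {
    if (is.null(x)) return(integer(0))
    if (is.character(x)) {
      n <<- nchar(x[[1L]])
      rna_encode(x)
    } else {
      if (is.null(n)) stop("n is required for integer codes")
      check_codes(as.integer(x), n)
    }
  }
  s <- to_codes(singles)
  d <- to_codes(duplexes)
  if (is.null(n)) stop("n must be supplied for an empty population")
  check_enum_cap(n, min(default_enum_cap(), 5L))
  mE <- 4^n
  Ns <- tabulate(s + 1L, nbins = mE)
  dc <- pmin(d, complement_code(d, n))
  Nd <- tabulate(dc + 1L, nbins = mE)
  structure(list(n = as.integer(n), Ns = Ns, Nd = Nd,
                 K = sum(Ns) + sum(Nd)),
            class = "rna_population")
}

#' @export
print.rna_population <- function(x, ...) {
  cat("RNA population: n =", x$n, ", K =", x$K, "molecules (",
      sum(x$Ns), "singles,", sum(x$Nd), "duplexes ),",
      sum(x$Ns > 0L), "unique single species,",
      sum(x$Nd > 0L), "unique duplex species\n")
  invisible(x)
}

#' Support sets of a population
#'
#' `X1` is the set of single-strand species present, `X2` the duplex species
#' present (canonical codes).
#'
#' @param pop an `rna_population`.
#' @return list with integer code vectors `X1` and `X2`.
#' @export
population_support <- function(pop) {
  list(X1 = which(pop$Ns > 0L) - 1L, X2 = which(pop$Nd > 0L) - 1L)
}

#' Volume fraction of high-fidelity sequences
#'
#' `V(t) = N_t(X_R) / K_t`: the fraction of molecules that are high-fidelity
#' single strands or duplexes containing a high-fidelity member.
#'
#' @param pop an `rna_population`.
#' @param R high-fidelity set (`high_fidelity_set`, character vector, or
#'   codes with the population's `n`).
#' @return scalar in `[0, 1]`.
#' @export
volume_fraction <- function(pop, R) {
  if (pop$K == 0L) stop("volume fraction undefined for an empty population")
  codes <- manifold_codes(R, pop$n)
  inR <- logical(4^pop$n)
  inR[codes + 1L] <- TRUE
  comp <- complement_code(0:(4^pop$n - 1L), pop$n)
  dupR <- inR | inR[comp + 1L]           # duplex {x, xc} touches R
  (sum(pop$Ns[inR]) + sum(pop$Nd[dupR])) / pop$K
}

manifold_codes <- function(R, n) {
  if (inherits(R, "high_fidelity_set")) {
    if (R$n != n) stop("manifold dimension differs from population")
    R$codes
  } else if (is.character(R)) {
    rna_encode(R)
  } else {
    check_codes(as.integer(R), n)
  }
}
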