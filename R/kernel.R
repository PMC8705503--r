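# Template-directed polymerization as a measure-kernel-function: the binomial
# mutation kernel Q, offspring sampling, the instantaneous domain measure
# nu_t over polymerase-template pairs, and the image measure mu_t = nu_t Q.

#' Binomial mutation-count distribution
#'
#' The number of mutations a polymerase with per-site fidelity `p_site` makes
#' on a length-`n` template is Binomial(n, 1 - p_site); with `p_site = 1` it
#' is a point mass at 0.
#'
#' @param p_site per-site copying fidelity in `(0, 1]`.
#' @param n sequence length.
#' @return numeric vector of length `n + 1`: P(i mutations), i = 0..n.
#' @export
mutation_count_pmf <- function(p_site, n) {
  if (p_site <= 0 || p_site > 1) stop("p_site must lie in (0, 1]")
  stats::dbinom(0:n, n, 1 - p_site)
}

#' One row of the polymerization transition kernel Q
#'
#' Probability over offspring sequences `z` for polymerase fidelity `p_site`
#' and template `y`: offspring at Hamming distance `i` from the template
#' complement `yc` carry total mass `choose(n,i) (1-p)^i p^(n-i)`, uniformly
#' over the `choose(n,i) 3^i` members of the level set, i.e.
#' `Q((x,y),{z}) = p^(n-i) ((1-p)/3)^i` with `i = h(yc, z)`. With `p = 1`
#' all mass sits on `{yc}`.
#'
#' @param p_site per-site fidelity in `(0, 1]`.
#' @param y template sequence (character or code).
#' @param n sequence length for a coded template.
#' @return numeric vector of length `4^n` over offspring codes; sums to 1.
#' @export
kernel_row <- function(p_site, y, n = NULL) {
  if (p_site <= 0 || p_site > 1) stop("p_site must lie in (0, 1]")
  if (is.character(y)) {
    n <- nchar(y[[1L]])
    y <- rna_encode(y)
  }
  check_enum_cap(n)
  check_codes(y, n)
  yc <- complement_code(y, n)
  i <- hamming_code(0:(4^n - 1L), yc, n)
  p_site^(n - i) * ((1 - p_site) / 3)^i
}

#' Sample an offspring sequence
#'
#' Draws one offspring of template `y` copied at per-site fidelity `p_site`:
#' each position emits the complement-correct base with probability `p_site`
#' and otherwise one of the three other bases uniformly. The marginal law is
#' exactly [kernel_row()].
#'
#' @inheritParams kernel_row
#' @return offspring code (integer) or sequence string matching the input
#'   representation.
#' @export
sample_offspring <- function(p_site, y, n = NULL) {
  chr <- is.character(y)
  if (chr) {
    n <- nchar(y[[1L]])
    y <- rna_encode(y)
  }
  z <- sample_offspring_code(p_site, y, n)
  if (chr) rna_decode(z, n) else z
}

# internal fast path: template code -> offspring code
sample_offspring_code <- function(p_site, y, n) {
  yc <- complement_code(y, n)
  if (p_site >= 1) return(yc)
  mut <- which(stats::runif(n) > p_site)
  if (length(mut) == 0L) return(yc)
  # shift the mutated base-4 digits by 1..3 (mod 4): uniform over alternatives
  for (pos in mut) {
    pw <- 4^(pos - 1L)
    digit <- (yc %/% pw) %% 4L
    yc <- yc + pw * ((digit + sample.int(3L, 1L)) %% 4L - digit)
  }
  as.integer(yc)
}

#' Instantaneous domain measure over polymerase-template pairs
#'
#' `nu_t{x, y} = k_rep(x, y) N(x) (N(y) - I(x=y)) / krep_total`: the
#' probability that the next polymerization event uses ordered pair (x, y).
#' Undefined (error of class `rnahit_undefined_measure`) when the total
#' replication rate is zero, e.g. a population holding a single molecule.
#'
#' @param pop an `rna_population`.
#' @param ls an `rna_landscape` of the same dimension.
#' @return object of class `domain_measure`: support vectors `x`, `y`
#'   (codes), normalized `weight`, and the `total_rate` (replicative mass).
#' @export
domain_measure <- function(pop, ls) {
  stopifnot(inherits(pop, "rna_population"), inherits(ls, "rna_landscape"))
  if (pop$n != ls$n) stop("population and landscape dimensions differ")
  sup <- which(pop$Ns > 0L)
  Nsup <- pop$Ns[sup]
  # W[i, j] = a f(x_i) N(x_i) s(x_i, x_j) (N(x_j) - I(i = j))
  W <- ls$a * outer(ls$Fv[sup] * Nsup, Nsup) * ls$Sm[sup, sup, drop = FALSE]
  diag(W) <- ls$a * ls$Fv[sup] * ls$sdiag[sup] * Nsup * (Nsup - 1)
  total <- sum(W)
  if (total <= 0)
    stop(structure(class = c("rnahit_undefined_measure", "error", "condition"),
                   list(message = "total replication rate is zero: domain measure undefined",
                        call = sys.call(-1))))
  idx <- which(W > 0, arr.ind = TRUE)
  structure(list(x = sup[idx[, 1L]] - 1L, y = sup[idx[, 2L]] - 1L,
                 weight = W[idx] / total, total_rate = total, n = pop$n),
            class = "domain_measure")
}

#' Image measure of polymerization output
#'
#' `mu_t = nu_t Q`: the probability law of the next polymerization product
#' over sequence space, plus its aggregation on the manifold partition
#' `H_i = {x : min(H(x,R), H(xc,R)) = i}` (the instantaneous information of
#' RNA polymerization).
#'
#' @param nu a `domain_measure`.
#' @param ls the `rna_landscape` providing fidelities and the partition.
#' @return object of class `image_measure`: `prob` (length `4^n`, sums to 1)
#'   and `class_mass` (mass per manifold class `H_0..H_n`).
#' @export
image_measure <- function(nu, ls) {
  stopifnot(inherits(nu, "domain_measure"), inherits(ls, "rna_landscape"))
  if (nu$n != ls$n) stop("dimension mismatch")
  n <- ls$n
  mE <- 4^n
  prob <- numeric(mE)
  p_pol <- ls$Pv[nu$x + 1L]
  # Q((x,y), z) depends on x only through p(x): group pairs by fidelity value
  for (p in unique(p_pol)) {
    sel <- p_pol == p
    tw <- numeric(mE)                       # template weights under nu
    agg <- tapply(nu$weight[sel], nu$y[sel], sum)
    tw[as.integer(names(agg)) + 1L] <- agg
    ysup <- which(tw > 0)
    if (p >= 1) {
      yc <- complement_code(ysup - 1L, n)
      prob[yc + 1L] <- prob[yc + 1L] + tw[ysup]
    } else {
      wK <- p^(n - (0:n)) * ((1 - p) / 3)^(0:n)
      # rows: template y (support), cols: offspring z; i = h(yc, z)
      Dyc <- ls$D[ls$comp[ysup] + 1L, , drop = FALSE]
      prob <- prob + as.vector(crossprod(matrix(wK[Dyc + 1L], nrow = length(ysup)),
                                         tw[ysup]))
    }
  }
  cm <- as.vector(tapply(prob, ls$class, sum))
  cm <- stats::setNames(as.numeric(cm), paste0("H", sort(unique(ls$class))))
  full <- stats::setNames(numeric(n + 1L), paste0("H", 0:n))
  full[names(cm)] <- cm
  structure(list(prob = prob, class_mass = full, n = n),
            class = "image_measure")
}
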