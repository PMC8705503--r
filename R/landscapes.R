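# High-fidelity manifold constructions and the fitness / similarity / fidelity
# landscapes entering the polymerization rate k_rep(x, y) = a f(x) s(x, y).

#' Build a high-fidelity set R
#'
#' R is either an explicit union of sequences or a product of per-position
#' allowed-base sets A_1 x ... x A_n. In the product form each position
#' independently admits all 4 bases with probability `q` and a single random
#' base otherwise, so the size is r = 4^(number of free positions).
#'
#' @param n sequence length (required for the product form or integer codes).
#' @param members explicit members: character vector or integer codes.
#' @param q fraction of unconstrained positions in the product form,
#'   in `[0, 1)`; `q = 0` gives a random singleton. Uses the current RNG.
#' @return object of class `high_fidelity_set` with fields `n`, `codes`,
#'   `size` and `construction`.
#' @examples
#' set.seed(1)
#' build_manifold(n = 3, q = 0)         # random singleton
#' build_manifold(members = c("AAA", "UUU"))
#' @export
build_manifold <- function(n = NULL, members = NULL, q = NULL) {
  if (!is.null(members)) {
    if (is.character(members)) {
      n <- nchar(members[[1L]])
      codes <- rna_encode(members)
    } else {
      if (is.null(n)) stop("n is required for integer codes")
      codes <- as.integer(members)
      check_codes(codes, n)
    }
    codes <- sort(unique(codes))
    if (length(codes) == 0L) stop("high-fidelity set must be non-empty")
    construction <- "union"
  } else if (!is.null(q)) {
    if (is.null(n)) stop("n is required for the product form")
    if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
    free <- stats::runif(n) < q
    base <- sample.int(4L, n, replace = TRUE) - 1L
    pos_sets <- lapply(seq_len(n), function(i) if (free[i]) 0:3 else base[i])
    grid <- expand.grid(pos_sets, KEEP.OUT.ATTRS = FALSE)
    codes <- sort(as.integer(as.matrix(grid) %*% 4^(seq_len(n) - 1L)))
    construction <- "product"
  } else {
    stop("supply either explicit members or a product-form fraction q")
  }
  structure(list(n = as.integer(n), codes = codes, size = length(codes),
                 construction = construction),
            class = "high_fidelity_set")
}

#' @export
print.high_fidelity_set <- function(x, ...) {
  cat("High-fidelity set R: r =", x$size, "sequences of length", x$n,
      paste0("(", x$construction, " form)\n"))
  show <- utils::head(x$codes, 8L)
  cat(" ", paste(rna_decode(show, x$n), collapse = " "),
      if (x$size > 8L) "...\n" else "\n")
  invisible(x)
}

#' Curvature from the landscape terminus value
#'
#' The tent landscape `exp(-k H)` is parameterized by its value at maximal
#' distance `H = n` (the terminus); `k = -log(terminus) / n` inverts that.
#'
#' @param terminus landscape value at distance n, in `(0, 1]`.
#' @param n sequence length.
#' @return curvature `k >= 0`.
#' @examples
#' curvature_from_terminus(0.01, 3)  # ~1.535
#' @export
curvature_from_terminus <- function(terminus, n) {
  if (any(terminus <= 0) || any(terminus > 1))
    stop("terminus must lie in (0, 1]")
  -log(terminus) / n
}

#' Tent landscape values
#'
#' `tent_fitness` evaluates `f_k(x, R) = exp(-k H(x, R))`; `tent_similarity`
#' evaluates `s_l(x, y) = exp(-l S(x, y))`; `fidelity` evaluates the per-site
#' copying fidelity `p_m(x, R)` of polymerase `x`, a tent (or linear)
#' landscape with its own curvature `m`. All values lie in `(0, 1]` and equal
#' 1 on the high-fidelity set (fitness, fidelity) or at spatial distance 0
#' (similarity).
#'
#' @param x,y sequences (character) or codes.
#' @param R high-fidelity set (see [manifold_distance()]).
#' @param k,l,m curvature parameters `>= 0`.
#' @param n sequence length for integer codes.
#' @return numeric vector of landscape values.
#' @export
tent_fitness <- function(x, R, k, n = NULL) {
  if (k < 0) stop("curvature must be >= 0")
  exp(-k * manifold_distance(x, R, n))
}

#' @rdname tent_fitness
#' @export
tent_similarity <- function(x, y, l, n = NULL) {
  if (l < 0) stop("curvature must be >= 0")
  exp(-l * spatial_distance(x, y, n))
}

#' Linear landscape values
#'
#' Affine counterparts of the tent landscapes: value 1 at distance 0 falling
#' linearly to `terminus` at distance `n`, i.e.
#' `f(x, R) = 1 + (terminus - 1) H(x, R) / n`.
#'
#' @param x,y sequences or codes.
#' @param R high-fidelity set.
#' @param terminus landscape value at maximal distance, in `(0, 1]`.
#' @param n sequence length for integer codes.
#' @return numeric vector of landscape values in `(0, 1]`.
#' @export
linear_fitness <- function(x, R, terminus, n = NULL) {
  if (terminus <= 0 || terminus > 1) stop("terminus must lie in (0, 1]")
  H <- manifold_distance(x, R, n)
  n <- if (inherits(R, "high_fidelity_set")) R$n else if (is.character(x)) nchar(x[[1L]]) else n
  1 + (terminus - 1) * H / n
}

#' @rdname linear_fitness
#' @export
linear_similarity <- function(x, y, terminus, n = NULL) {
  if (terminus <= 0 || terminus > 1) stop("terminus must lie in (0, 1]")
  if (is.character(x)) n <- nchar(x[[1L]])
  S <- spatial_distance(x, y, n)
  1 + (terminus - 1) * S / n
}

#' Per-site polymerase fidelity
#'
#' @rdname tent_fitness
#' @param form `"tent"` or `"linear"`.
#' @export
fidelity <- function(x, R, m, n = NULL, form = c("tent", "linear")) {
  form <- match.arg(form)
  if (form == "tent") {
    tent_fitness(x, R, m, n)
  } else {
    linear_fitness(x, R, exp(-m * (if (inherits(R, "high_fidelity_set")) R$n else n)), n)
  }
}

#' Assemble a landscape over sequence space
#'
#' Bundles the high-fidelity set with the fitness, similarity and fidelity
#' landscapes and precomputes dense lookup tables over all `4^n` sequences
#' (fitness vector, fidelity vector, similarity matrix, Hamming matrix and
#' the manifold partition), which the simulator and the mean-field ODE use.
#'
#' @param R high-fidelity set (`high_fidelity_set`, character vector or codes
#'   with `n`).
#' @param n sequence length for integer codes.
#' @param form landscape form, `"tent"` or `"linear"`. For `"tent"` the
#'   curvatures `k`, `l`, `m` are exponents; for `"linear"` the termini are
#'   used directly (`exp(-k n)` etc.), matching the convention that both
#'   forms agree at distances 0 and n.
#' @param k,l fitness and similarity curvatures (tent form), `>= 0`.
#' @param m fidelity curvature; default `-log(0.25)/n` so the least fit
#'   sequences copy at random chance 0.25.
#' @param terminus_f,terminus_s,terminus_p linear-form termini in `(0, 1]`;
#'   default `exp(-k n)` etc. so a tent landscape and its linear counterpart
#'   share endpoints.
#' @param a replication rate scale (`k_rep = a f s`), `> 0`.
#' @param similarity `"distance"` for the spatial-distance landscape or
#'   `"constant"` for the trivial similarity `s(x, y) = b`.
#' @param b constant similarity value in `(0, 1]` when
#'   `similarity = "constant"`.
#' @return object of class `rna_landscape`.
#' @examples
#' R <- build_manifold(members = "AAA")
#' ls <- landscape(R, k = curvature_from_terminus(0.01, 3),
#'                 l = curvature_from_terminus(0.01, 3))
#' @export
landscape <- function(R, n = NULL, form = c("tent", "linear"),
                      k = 0, l = 0, m = NULL, a = 10,
                      terminus_f = NULL, terminus_s = NULL, terminus_p = NULL,
                      similarity = c("distance", "constant"), b = 1) {
  form <- match.arg(form)
  similarity <- match.arg(similarity)
  if (!inherits(R, "high_fidelity_set"))
    R <- build_manifold(n = n, members = R)
  n <- R$n
  if (is.null(m)) m <- curvature_from_terminus(0.25, n)
  if (a <= 0) stop("replication scale a must be > 0")
  if (k < 0 || l < 0 || m < 0) stop("curvatures must be >= 0")
  if (b <= 0 || b > 1) stop("constant similarity b must lie in (0, 1]")
  if (is.null(terminus_f)) terminus_f <- exp(-k * n)
  if (is.null(terminus_s)) terminus_s <- exp(-l * n)
  if (is.null(terminus_p)) terminus_p <- exp(-m * n)

  check_enum_cap(n, min(default_enum_cap(), 5L))
  mE <- 4^n
  codes <- 0:(mE - 1L)
  comp <- complement_code(codes, n)
  D <- hamming_matrix(n)
  Hman <- manifold_distance(codes, R$codes, n)
  cls <- pmin(Hman, Hman[comp + 1L])
  Smat_dist <- pmin(D, D[, comp + 1L])           # S(x, y)
  shape <- function(dist, curv, term) {
    if (form == "tent") exp(-curv * dist) else 1 + (term - 1) * dist / n
  }
  Fv <- shape(Hman, k, terminus_f)
  Pv <- shape(Hman, m, terminus_p)
  Sm <- if (similarity == "constant") {
    matrix(b, mE, mE)
  } else {
    shape(Smat_dist, l, terminus_s)
  }
  structure(list(
    n = n, R = R, form = form, similarity = similarity, b = b,
    k = k, l = l, m = m, a = a,
    terminus_f = terminus_f, terminus_s = terminus_s, terminus_p = terminus_p,
    codes = codes, comp = comp, D = D, Hman = Hman, class = cls,
    Fv = Fv, Pv = Pv, Sm = Sm, sdiag = diag(Sm),
    in_R = codes %in% R$codes
  ), class = "rna_landscape")
}

#' @export
print.rna_landscape <- function(x, ...) {
  cat("RNA landscape: n =", x$n, ", |R| =", x$R$size, ", form =", x$form, "\n")
  cat("  k =", signif(x$k, 5), " l =", signif(x$l, 5), " m =", signif(x$m, 5),
      " a =", x$a, " similarity =", x$similarity, "\n")
  invisible(x)
}

#' Set the replication scale of a landscape
#'
#' @param ls an `rna_landscape`.
#' @param a new replication scale, `> 0`.
#' @return the landscape with `a` replaced.
#' @export
set_replication_scale <- function(ls, a) {
  stopifnot(inherits(ls, "rna_landscape"))
  if (a <= 0) stop("replication scale a must be > 0")
  ls$a <- a
  ls
}
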