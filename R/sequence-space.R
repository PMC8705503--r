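# Sequence space E = {A,U,G,C}^n, integer base-4 encoded.
#
# Codes: A=0, U=1, G=2, C=3, position 1 in the least-significant base-4 digit,
# so a sequence is an integer in [0, 4^n). Complementation (A<->U, C<->G) is
# XOR of every base-4 digit with 1, i.e. XOR with the repunit (4^n - 1)/3.

RNA_BASES <- c("A", "U", "G", "C")

#' Encode RNA sequences as integer codes
#'
#' Sequences of fixed length `n` over the alphabet A, U, G, C are stored as
#' base-4 integers (A=0, U=1, G=2, C=3; position 1 is the least-significant
#' digit), so a sequence is a single integer in `[0, 4^n)`.
#'
#' @param x character vector of sequences, all of the same length.
#' @return named list with integer vector `code` and the common length `n`
#'   is not returned; `rna_encode` returns the integer codes.
#' @examples
#' rna_encode(c("AUG", "AAA"))
#' @export
rna_encode <- function(x) {
  x <- toupper(as.character(x))
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("all sequences must have the same length")
  n <- lens[[1L]]
  if (n < 1L) stop("sequences must have length >= 1")
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) {
    idx <- match(ch, RNA_BASES)
    if (anyNA(idx))
      stop("invalid base symbol: ", paste(unique(ch[is.na(idx)]), collapse = ", "),
           " (alphabet is A, U, G, C)")
    as.integer(sum((idx - 1L) * 4^(seq_len(n) - 1L)))
  }, integer(1))
}

#' Decode integer codes back to RNA sequence strings
#'
#' @param code integer vector of sequence codes in `[0, 4^n)`.
#' @param n sequence length.
#' @return character vector of sequences over A, U, G, C.
#' @export
rna_decode <- function(code, n) {
  check_codes(code, n)
  vapply(code, function(cd) {
    digits <- integer(n)
    for (i in seq_len(n)) {
      digits[i] <- cd %% 4L
      cd <- cd %/% 4L
    }
    paste(RNA_BASES[digits + 1L], collapse = "")
  }, character(1))
}

check_codes <- function(code, n) {
  if (any(is.na(code)) || any(code < 0L) || any(code >= 4^n))
    stop("sequence codes must lie in [0, 4^n)")
  invisible(code)
}

#' Complement of RNA sequences
#'
#' Element-wise base pairing A<->U, C<->G (not reverse-complemented). The map
#' is an involution with no fixed point. Character input returns characters;
#' integer input is interpreted as codes and requires `n`.
#'
#' @param x character vector of sequences, or integer codes.
#' @param n sequence length, required for integer codes.
#' @return complemented sequences, same representation as the input.
#' @examples
#' rna_complement("AUG")  # "UAC"
#' @export
rna_complement <- function(x, n = NULL) {
  if (is.character(x)) {
    code <- rna_encode(x)
    n <- nchar(x[[1L]])
    return(rna_decode(complement_code(code, n), n))
  }
  if (is.null(n)) stop("n is required for integer codes")
  check_codes(x, n)
  complement_code(as.integer(x), n)
}

complement_code <- function(code, n) {
  bitwXor(as.integer(code), as.integer((4^n - 1) / 3))
}

as_codes <- function(x, n = NULL) {
  if (is.character(x)) {
    code <- rna_encode(x)
    attr(code, "n") <- nchar(x[[1L]])
    return(code)
  }
  if (is.null(n)) stop("n is required for integer codes")
  check_codes(as.integer(x), n)
  code <- as.integer(x)
  attr(code, "n") <- as.integer(n)
  code
}

#' Hamming distance between sequences
#'
#' Number of positions at which two equal-length sequences differ; satisfies
#' `h(x, x) = 0` and `h(x, complement(x)) = n`.
#'
#' @param x,y sequences (character) or integer codes (then supply `n`).
#' @param n sequence length for integer codes.
#' @return integer vector of distances in `0..n`.
#' @examples
#' hamming_distance("AAG", "AUG")  # 1
#' @export
hamming_distance <- function(x, y, n = NULL) {
  if (is.character(x) != is.character(y))
    stop("x and y must use the same representation")
  if (is.character(x)) {
    if (any(nchar(x) != nchar(y))) stop("sequence lengths differ")
    n <- nchar(x[[1L]])
    x <- rna_encode(x); y <- rna_encode(y)
  } else {
    if (is.null(n)) stop("n is required for integer codes")
    check_codes(x, n); check_codes(y, n)
  }
  hamming_code(x, y, n)
}

hamming_code <- function(x, y, n) {
  x <- as.integer(x); y <- as.integer(y)
  d <- integer(max(length(x), length(y)))
  if (length(x) < length(d)) x <- rep_len(x, length(d))
  if (length(y) < length(d)) y <- rep_len(y, length(d))
  for (i in seq_len(n)) {
    d <- d + ((x %% 4L) != (y %% 4L))
    x <- x %/% 4L
    y <- y %/% 4L
  }
  d
}

#' Distance to the high-fidelity manifold
#'
#' `H(x, R) = min over y in R of h(x, y)`: the Hamming distance from a
#' sequence to the nearest member of the high-fidelity set R.
#'
#' @param x sequences (character) or codes.
#' @param R high-fidelity set: character vector, integer codes, or a
#'   `high_fidelity_set` object.
#' @param n sequence length for integer codes.
#' @return integer vector of distances in `0..n`.
#' @export
manifold_distance <- function(x, R, n = NULL) {
  if (length(R) == 0L && !inherits(R, "high_fidelity_set"))
    stop("high-fidelity set R must be non-empty")
  if (inherits(R, "high_fidelity_set")) {
    n0 <- R$n
    R <- R$codes
  } else if (is.character(R)) {
    n0 <- nchar(R[[1L]])
    R <- rna_encode(R)
  } else {
    n0 <- n
  }
  if (length(R) == 0L) stop("high-fidelity set R must be non-empty")
  if (is.character(x)) {
    if (any(nchar(x) != n0)) stop("sequence lengths differ from R")
    x <- rna_encode(x)
  }
  n <- n0
  check_codes(x, n); check_codes(R, n)
  out <- rep.int(n, length(x))
  for (y in R) out <- pmin(out, hamming_code(x, y, n))
  out
}

#' Spatial (complement-invariant) distance between sequences
#'
#' `S(x, y) = min of h(x,y), h(x,yc), h(xc,y), h(xc,yc)`. Since element-wise
#' complementation preserves mismatches, this reduces to
#' `min(h(x,y), h(x,yc))`. S is symmetric and invariant under complementing
#' either argument; `S(x, complement(x)) = 0`.
#'
#' @inheritParams hamming_distance
#' @return integer vector of distances in `0..n`.
#' @export
spatial_distance <- function(x, y, n = NULL) {
  if (is.character(x)) {
    if (any(nchar(x) != nchar(y))) stop("sequence lengths differ")
    n <- nchar(x[[1L]])
    x <- rna_encode(x); y <- rna_encode(y)
  } else {
    if (is.null(n)) stop("n is required for integer codes")
  }
  check_codes(x, n); check_codes(y, n)
  yc <- complement_code(y, n)
  pmin(hamming_code(x, y, n), hamming_code(x, yc, n))
}

default_enum_cap <- function() getOption("rnahit.enum_cap", 8L)

check_enum_cap <- function(n, cap = default_enum_cap()) {
  if (n > cap)
    stop("full enumeration of 4^", n, " sequences exceeds the cap (n <= ", cap,
         "); compute distances on demand instead")
  invisible(n)
}

#' All sequence codes of dimension n
#'
#' @param n sequence length (guarded by the enumeration cap, default 8).
#' @return integer vector `0:(4^n - 1)`.
#' @export
all_codes <- function(n) {
  check_enum_cap(n)
  0:(4^n - 1L)
}

#' Full Hamming distance matrix over sequence space
#'
#' @param n sequence length (enumeration-capped).
#' @return `4^n x 4^n` integer matrix `D[x+1, y+1] = h(x, y)`.
#' @export
hamming_matrix <- function(n) {
  check_enum_cap(n, min(default_enum_cap(), 6L))
  m <- 4^n
  codes <- 0:(m - 1L)
  D <- matrix(0L, m, m)
  x <- codes
  for (i in seq_len(n)) {
    digit <- x %% 4L
    D <- D + outer(digit, digit, "!=")
    x <- x %/% 4L
  }
  storage.mode(D) <- "integer"
  D
}

#' Level-set partition of sequence space
#'
#' Partitions E by Hamming distance to a reference. For a single template
#' `y`, class `H_i(y) = {x : h(yc, x) = i}` (distance to the template's
#' complement), with `|H_i| = choose(n, i) * 3^i`. For a high-fidelity set R,
#' class `H_i = {x : min(H(x,R), H(xc,R)) = i}` (the manifold partition used
#' for concentration and polymerase-output measures).
#'
#' @param reference a single sequence (template) or a high-fidelity set
#'   (character vector of length > 1, code vector, or `high_fidelity_set`).
#' @param n sequence length for integer codes.
#' @param type `"template"` or `"manifold"`; inferred from the reference when
#'   missing (a single sequence is a template, anything larger a manifold).
#' @return object of class `level_set_partition` with the class index of
#'   every sequence (`class`, in `0..n`) and class sizes (`sizes`).
#' @export
level_sets <- function(reference, n = NULL, type = NULL) {
  if (inherits(reference, "high_fidelity_set")) {
    n <- reference$n
    codes <- reference$codes
    if (is.null(type)) type <- "manifold"
  } else if (is.character(reference)) {
    n <- nchar(reference[[1L]])
    codes <- rna_encode(reference)
    if (is.null(type)) type <- if (length(codes) == 1L) "template" else "manifold"
  } else {
    if (is.null(n)) stop("n is required for integer codes")
    codes <- as.integer(reference)
    check_codes(codes, n)
    if (is.null(type)) type <- if (length(codes) == 1L) "template" else "manifold"
  }
  check_enum_cap(n)
  type <- match.arg(type, c("template", "manifold"))
  all <- 0:(4^n - 1L)
  cls <- if (type == "template") {
    hamming_code(all, complement_code(codes[[1L]], n), n)
  } else {
    H <- manifold_distance(all, codes, n)
    pmin(H, H[complement_code(all, n) + 1L])
  }
  sizes <- tabulate(cls + 1L, nbins = n + 1L)
  structure(list(n = n, type = type, reference = codes, class = cls,
                 sizes = stats::setNames(sizes, paste0("H", 0:n))),
            class = "level_set_partition")
}

#' @export
print.level_set_partition <- function(x, ...) {
  cat("Level-set partition (", x$type, ") of E, n = ", x$n, "\n", sep = "")
  print(x$sizes)
  invisible(x)
}
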