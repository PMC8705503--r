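# Small shared fixtures, built in code.

# singleton-R tent landscape at n = 2 or 3 with the standard curvatures
tiny_landscape <- function(n = 3, R_seq = strrep("A", n), terminus = 0.01,
                           a = 10, ...) {
  k <- curvature_from_terminus(terminus, n)
  landscape(build_manifold(members = R_seq), k = k, l = k, a = a, ...)
}

# frozen mixed population: complementary singles plus a duplex
frozen_population <- function(n = 3) {
  population(singles = c("AAG", "AAG", "UUC", "UUC", "UUC", "GAU"),
             duplexes = c("AAA", "AGA"))
}

# brute-force kernel row: enumerate per-position mutation outcomes
brute_kernel_row <- function(p, y, n) {
  yc <- rna_encode(rna_complement(rna_decode(y, n)))
  probs <- numeric(4^n)
  digits <- integer(n)
  cd <- yc
  for (i in seq_len(n)) { digits[i] <- cd %% 4L; cd <- cd %/% 4L }
  per_pos <- lapply(seq_len(n), function(i) {
    pr <- rep((1 - p) / 3, 4)
    pr[digits[i] + 1L] <- p
    pr
  })
  grid <- expand.grid(lapply(seq_len(n), function(i) 0:3))
  for (r in seq_len(nrow(grid))) {
    z <- sum(unlist(grid[r, ]) * 4^(seq_len(n) - 1L))
    probs[z + 1L] <- prod(vapply(seq_len(n),
                                 function(i) per_pos[[i]][grid[r, i] + 1L],
                                 numeric(1)))
  }
  probs
}
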