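test_that("complementation pairs A<->U, C<->G and is a fixed-point-free involution", {
  expect_equal(rna_complement("AUG"), "UAC")
  expect_equal(rna_complement("AAAA"), "UUUU")
  expect_error(rna_encode("AXG"), "invalid base")
  set.seed(11)
  for (n in 2:5) {
    codes <- sample.int(4^n, 20, replace = TRUE) - 1L
    cc <- rna_complement(codes, n)
    expect_equal(rna_complement(cc, n), codes)   # involution
    expect_true(all(cc != codes))                # no fixed point
  }
})

test_that("hamming distance matches its defining properties", {
  expect_equal(hamming_distance("AAG", "AUG"), 1L)
  expect_equal(hamming_distance("AUG", "AUG"), 0L)
  n <- 4
  set.seed(12)
  x <- sample.int(4^n, 50, replace = TRUE) - 1L
  expect_equal(hamming_distance(x, x, n), rep(0L, 50))
  # h(x, xc) = n always
  expect_equal(hamming_distance(x, rna_complement(x, n), n), rep(n, 50))
  # symmetry and triangle inequality on random triples
  y <- sample.int(4^n, 50, replace = TRUE) - 1L
  z <- sample.int(4^n, 50, replace = TRUE) - 1L
  expect_equal(hamming_distance(x, y, n), hamming_distance(y, x, n))
  expect_true(all(hamming_distance(x, z, n) <=
                    hamming_distance(x, y, n) + hamming_distance(y, z, n)))
  expect_error(hamming_distance("AA", "AAA"), "length")
})

test_that("manifold distance is the minimum over members (brute force)", {
  expect_equal(manifold_distance("AAU", c("AAA")), 1L)
  expect_equal(manifold_distance("UUA", c("AAA", "UUU")), 1L)
  expect_equal(manifold_distance("AAA", c("AAA", "UUU")), 0L)
  set.seed(13)
  n <- 3
  R <- sample.int(4^n, 5) - 1L
  x <- sample.int(4^n, 30, replace = TRUE) - 1L
  brute <- vapply(x, function(xi) min(hamming_distance(rep(xi, length(R)), R, n)),
                  integer(1))
  expect_equal(manifold_distance(x, R, n), brute)
  expect_error(manifold_distance("AAA", character(0)), "non-empty")
})

test_that("spatial distance is the min of the four hamming terms and complement-invariant", {
  expect_equal(spatial_distance("AAA", "AAA"), 0L)
  expect_equal(spatial_distance("AAA", "AAU"), 1L)
  n <- 3
  set.seed(14)
  x <- sample.int(4^n, 40, replace = TRUE) - 1L
  y <- sample.int(4^n, 40, replace = TRUE) - 1L
  xc <- rna_complement(x, n); yc <- rna_complement(y, n)
  brute <- pmin(hamming_distance(x, y, n), hamming_distance(x, yc, n),
                hamming_distance(xc, y, n), hamming_distance(xc, yc, n))
  expect_equal(spatial_distance(x, y, n), brute)
  expect_equal(spatial_distance(x, xc, n), rep(0L, 40))      # S(x, xc) = 0
  expect_equal(spatial_distance(xc, y, n), spatial_distance(x, y, n))
  expect_equal(spatial_distance(x, yc, n), spatial_distance(x, y, n))
})

test_that("level sets partition E with the binomial class sizes", {
  for (n in 2:4) {
    y <- rna_decode(sample.int(4^n, 1) - 1L, n)
    p <- level_sets(y)
    expect_equal(sum(p$sizes), 4^n)
    expect_equal(unname(p$sizes), choose(n, 0:n) * 3^(0:n))
    # H_0(y) is exactly {complement(y)}
    expect_equal(rna_decode(which(p$class == 0L) - 1L, n), rna_complement(y))
  }
  # manifold partition: classes disjoint, union E, complement-invariant
  R <- build_manifold(members = c("AAA", "GGC"))
  pm <- level_sets(R)
  expect_equal(sum(pm$sizes), 64)
  comp_cls <- pm$class[rna_complement(0:63, 3) + 1L]
  expect_equal(pm$class, comp_cls)
  expect_error(level_sets(strrep("A", 12)), "cap")
})
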