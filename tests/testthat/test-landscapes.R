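test_that("curvature and terminus are inverse parameterizations", {
  expect_equal(curvature_from_terminus(0.01, 3), -log(0.01) / 3)
  expect_equal(curvature_from_terminus(1, 5), 0)
  expect_equal(curvature_from_terminus(exp(-4), 4), 1)
  expect_error(curvature_from_terminus(0, 3), "terminus")
  expect_error(curvature_from_terminus(1.2, 3), "terminus")
  # evaluating the tent at distance n returns the terminus
  k <- curvature_from_terminus(0.01, 3)
  expect_equal(tent_fitness("UUU", c("AAA"), k), 0.01)
})

test_that("tent landscapes are 1 on R and decay exponentially", {
  R <- build_manifold(members = "AAA")
  k <- curvature_from_terminus(0.01, 3)
  expect_equal(tent_fitness("AAA", R, k), 1)
  expect_equal(tent_fitness("AAU", R, k), exp(-k))
  expect_equal(tent_fitness("AAA", R, 0), 1)
  set.seed(21)
  x <- sample.int(64, 20, TRUE) - 1L; y <- sample.int(64, 20, TRUE) - 1L
  expect_equal(tent_similarity(x, x, 0.7, 3), rep(1, 20))
  expect_equal(tent_similarity(x, rna_complement(x, 3), 0.7, 3), rep(1, 20))
  expect_equal(tent_similarity(x, y, 0.7, 3), tent_similarity(y, x, 0.7, 3))
})

test_that("linear landscapes interpolate 1 to the terminus and agree with tent at the endpoints", {
  R <- build_manifold(members = "AAA")
  expect_equal(linear_fitness("AAA", R, 0.01), 1)
  expect_equal(linear_fitness("UUU", R, 0.01), 0.01)
  expect_equal(linear_fitness("GGG", R, 1), 1)
  k <- curvature_from_terminus(0.05, 3)
  # same endpoints as the tent parameterized to the same terminus
  expect_equal(linear_fitness("AAA", R, 0.05), tent_fitness("AAA", R, k))
  expect_equal(linear_fitness("UUU", R, 0.05), tent_fitness("UUU", R, k))
})

test_that("fidelity is a probability, 1 on R, terminus 0.25 at maximal distance", {
  R <- build_manifold(members = "AAA")
  m <- curvature_from_terminus(0.25, 3)
  expect_equal(fidelity("AAA", R, m), 1)
  expect_equal(fidelity("UUU", R, m), 0.25)
  p <- fidelity(0:63, R, m, n = 3)
  expect_true(all(p > 0 & p <= 1))
  # monotone non-increasing in manifold distance
  H <- manifold_distance(0:63, R)
  expect_true(all(diff(tapply(p, H, unique)) < 0))
})

test_that("manifold constructions give the product / union sizes", {
  expect_equal(build_manifold(members = c("AAA", "UUU", "AAA"))$size, 2L)
  set.seed(22)
  m1 <- build_manifold(n = 3, q = 0)
  expect_equal(m1$size, 1L)
  # product form size is 4^(free positions)
  set.seed(23)
  reps <- replicate(40, build_manifold(n = 4, q = 0.5)$size)
  expect_true(all(reps %in% 4^(0:4)))
  expect_error(build_manifold(n = 3), "members or")
})

test_that("the assembled landscape keeps k_rep in (0, a] and matches elementary evaluators", {
  set.seed(24)
  ls <- tiny_landscape(n = 3, terminus = 0.05, a = 7)
  krep <- ls$a * outer(ls$Fv, rep(1, 64)) * ls$Sm
  expect_true(all(krep > 0 & krep <= ls$a + 1e-12))
  x <- sample.int(64, 25, TRUE) - 1L; y <- sample.int(64, 25, TRUE) - 1L
  expect_equal(ls$Fv[x + 1L], tent_fitness(x, ls$R, ls$k, 3))
  expect_equal(ls$Sm[cbind(x + 1L, y + 1L)], tent_similarity(x, y, ls$l, 3))
  expect_equal(ls$Pv[x + 1L], fidelity(x, ls$R, ls$m, 3))
  # constant-similarity mode
  lsb <- landscape(build_manifold(members = "AA"), k = 1, l = 1,
                   similarity = "constant", b = 0.4)
  expect_true(all(lsb$Sm == 0.4))
})
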