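test_that("mutation counts are Binomial(n, 1 - p), degenerate at p = 1", {
  expect_equal(mutation_count_pmf(1, 4), c(1, 0, 0, 0, 0))
  expect_equal(mutation_count_pmf(0.5, 2), c(0.25, 0.5, 0.25))
  pmf <- mutation_count_pmf(0.7, 6)
  expect_equal(sum(pmf), 1)
  expect_equal(sum((0:6) * pmf), 6 * 0.3)          # mean n(1-p)
  expect_equal(sum((0:6)^2 * pmf) - (6 * 0.3)^2, 6 * 0.7 * 0.3)
  expect_error(mutation_count_pmf(0, 3), "p_site")
})

test_that("kernel rows match brute-force enumeration and the binomial level-set masses", {
  for (n in 2:3) {
    set.seed(30 + n)
    for (p in c(0.35, 0.7, 0.95)) {
      y <- sample.int(4^n, 1) - 1L
      q <- kernel_row(p, y, n)
      expect_equal(sum(q), 1)
      expect_equal(q, brute_kernel_row(p, y, n))
      # mass on H_i(y) is exactly Binomial(n, 1-p)
      i <- hamming_distance(0:(4^n - 1L), rep(rna_complement(y, n), 4^n), n)
      expect_equal(as.vector(tapply(q, i, sum)), mutation_count_pmf(p, n))
      # uniform within each level set
      expect_true(all(tapply(q, i, function(v) diff(range(v))) < 1e-15))
    }
    # p = 1: all mass on the template complement
    y <- sample.int(4^n, 1) - 1L
    q1 <- kernel_row(1, y, n)
    expect_equal(which(q1 > 0) - 1L, rna_complement(y, n))
  }
})

test_that("offspring sampling has the kernel-row law", {
  expect_equal(sample_offspring(1, "AUG"), "UAC")
  n <- 2
  y <- rna_encode("GA")
  p <- 0.7
  set.seed(33)
  draws <- replicate(20000, sample_offspring(p, y, n))
  obs <- tabulate(draws + 1L, nbins = 4^n)
  expected <- kernel_row(p, y, n) * length(draws)
  gof <- suppressWarnings(chisq.test(obs, p = kernel_row(p, y, n)))
  expect_gt(gof$p.value, 1e-4)
  # level-set frequencies within 3 sigma of Binomial(n, 1-p)
  i <- hamming_distance(draws, rep(rna_complement(y, n), length(draws)), n)
  for (cl in 0:n) {
    pr <- mutation_count_pmf(p, n)[cl + 1L]
    expect_lt(abs(sum(i == cl) - length(draws) * pr),
              3 * sqrt(length(draws) * pr * (1 - pr)) + 1)
  }
})

test_that("the domain measure weights pairs by k_rep N(x)(N(y) - I(x=y))", {
  ls <- tiny_landscape(n = 3)
  # one lone molecule: undefined measure
  lone <- population("AAG")
  expect_error(domain_measure(lone, ls), class = "rnahit_undefined_measure")
  # two distinct molecules, constant similarity: weight ratio f(x)/f(y)
  lsb <- landscape(build_manifold(members = "AAA"), k = 1.2, l = 0,
                   similarity = "constant", b = 1)
  pop2 <- population(c("AAG", "GGC"))
  nu <- domain_measure(pop2, lsb)
  expect_equal(sum(nu$weight), 1)
  w_xy <- nu$weight[nu$x == rna_encode("AAG")]
  w_yx <- nu$weight[nu$x == rna_encode("GGC")]
  expect_equal(w_xy / w_yx,
               tent_fitness("AAG", lsb$R, 1.2) / tent_fitness("GGC", lsb$R, 1.2))
})

test_that("the image measure equals the dense nu Q product", {
  set.seed(35)
  for (n in 2:3) {
    ls <- tiny_landscape(n = n, terminus = 0.05)
    pop <- population(sample.int(4^n, 6, replace = TRUE) - 1L, n = n)
    nu <- domain_measure(pop, ls)
    mu <- image_measure(nu, ls)
    expect_equal(sum(mu$prob), 1)
    expect_equal(sum(mu$class_mass), 1)
    # dense oracle: sum over support pairs of weight * kernel_row
    dense <- numeric(4^n)
    for (r in seq_along(nu$weight))
      dense <- dense + nu$weight[r] * kernel_row(ls$Pv[nu$x[r] + 1L], nu$y[r], n)
    expect_equal(mu$prob, dense, tolerance = 1e-12)
    expect_equal(unname(mu$class_mass),
                 as.vector(rowsum(dense, ls$class)), tolerance = 1e-12)
  }
})

test_that("with p = 1 everywhere the image measure sits on template complements", {
  # R = E makes every sequence high-fidelity (p = 1)
  n <- 2
  ls <- landscape(build_manifold(n = n, members = 0:(4^n - 1L)), k = 1, l = 1)
  expect_true(all(ls$Pv == 1))
  pop <- population(c("AU", "GA", "GA"))
  nu <- domain_measure(pop, ls)
  mu <- image_measure(nu, ls)
  dense <- numeric(4^n)
  for (r in seq_along(nu$weight)) {
    z <- rna_complement(nu$y[r], n)
    dense[z + 1L] <- dense[z + 1L] + nu$weight[r]
  }
  expect_equal(mu$prob, dense)
})
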