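test_that("channel rates evaluate the propensity sums on small hand states", {
  ls <- tiny_landscape(n = 3)
  rates <- reaction_rates(kds = 2, kss = 3)
  # 2 copies of x and 3 of xc: ds rate = 0.5(2*2*3 + 2*3*2) = 12
  pop <- population(c("AAG", "AAG", "UUC", "UUC", "UUC"))
  cr <- channel_rates(pop, ls, rates)
  expect_equal(unname(cr[["ds_form"]]), 12)
  # a single molecule: no replication possible (self-pair excluded)
  expect_equal(unname(channel_rates(population("AAG"), ls, rates)[["rna_poly"]]), 0)
  # duplex-only population: only dissociation
  podup <- population(duplexes = c("AAA", "AAA", "GGC"), n = 3)
  crd <- channel_rates(podup, ls, rates)
  expect_equal(unname(crd[["ds_dissoc"]]), 3 * 3)
  expect_equal(unname(crd[["rna_poly"]]), 0)
  expect_equal(unname(crd[["ds_form"]]), 0)
})

test_that("support-restricted rates equal the naive full-space sums", {
  set.seed(41)
  rates <- reaction_rates(kds = 1.5, kss = 0.7, kdecay = 0.2,
                          kclay_o = 0.3, kclay_p = 0.9)
  for (rep_i in 1:3) {
    n <- sample(2:3, 1)
    ls <- tiny_landscape(n = n, R_seq = rna_decode(sample.int(4^n, 1) - 1L, n),
                         terminus = 0.05)
    pop <- population(singles = sample.int(4^n, 8, TRUE) - 1L,
                      duplexes = sample.int(4^n, 3, TRUE) - 1L, n = n)
    expect_equal(channel_rates(pop, ls, rates),
                 channel_rates_naive(pop, ls, rates), tolerance = 1e-12)
  }
})

test_that("single steps respect the reaction stoichiometry", {
  ls <- tiny_landscape(n = 3)
  rates <- reaction_rates()
  # ds formation is the only possible channel for a complementary pair
  pop <- population(c("AAG", "UUC"))
  ls0 <- tiny_landscape(n = 3, a = 1e-12)  # suppress replication
  set.seed(42)
  st <- ssa_step(pop, ls0, rates)
  expect_equal(st$event$channel, "ds_form")
  expect_equal(st$pop$K, pop$K - 1L)
  expect_equal(sum(st$pop$Ns), 0L)
  expect_equal(sum(st$pop$Nd), 1L)
  # dissociation restores the strands
  st2 <- ssa_step(st$pop, ls0, rates)
  expect_equal(st2$event$channel, "ds_dissoc")
  expect_equal(st2$pop$Ns, pop$Ns)
  # replication with p = 1 adds exactly the template complement
  lsE <- landscape(build_manifold(n = 2, members = 0:15), k = 1, l = 1, a = 10)
  popr <- population(c("AU", "GC"))
  set.seed(43)
  str <- ssa_step(popr, lsE, reaction_rates(kds = 0, kss = 0))
  expect_equal(str$event$channel, "rna_poly")
  expect_equal(str$event$prod, rna_complement(str$event$r2, 2))
  expect_equal(str$pop$K, 3L)
})

test_that("an absorbing state halts cleanly and budget 0 yields no events", {
  ls <- tiny_landscape(n = 3, a = 1)
  lone <- population("GAU")
  expect_null(ssa_step(lone, ls, reaction_rates(kds = 1, kss = 1)))
  tr <- simulate_population(ls, lone, reaction_rates(), budget = 50, seed = 1)
  expect_equal(tr$stopped, "absorbed")
  expect_equal(tr$n_events, 0L)
  tr0 <- simulate_population(ls, frozen_population(), reaction_rates(),
                             budget = 0, seed = 1)
  expect_equal(nrow(tr0$events), 0L)
  expect_equal(tr0$final$Ns, frozen_population()$Ns)
})

test_that("with only clay oligomerization every event adds one molecule", {
  ls <- tiny_landscape(n = 3, a = 1e-300)
  rates <- reaction_rates(kds = 0, kss = 0, kclay_o = 2)
  init <- population(c("AAG", "GAU"))
  tr <- simulate_population(ls, init, rates, budget = 40, seed = 5)
  expect_equal(tr$n_events, 40L)
  expect_true(all(tr$events$channel == "clay_oligo"))
  expect_equal(tr$final$K, init$K + 40L)
})

test_that("bookkeeping invariants hold along a mixed trajectory", {
  set.seed(44)
  ls <- tiny_landscape(n = 3, terminus = 0.05)
  init <- init_population(3, 8, ls$R, avoid_R = TRUE)
  tr <- simulate_population(ls, init, reaction_rates(kds = 1, kss = 1),
                            budget = 300, seed = 45)
  # K equals total molecule count after every event (replay)
  vf <- replay_volume_fraction(tr)
  expect_equal(vf$K[-1L], tr$events$K)
  expect_equal(tr$final$K, sum(tr$final$Ns) + sum(tr$final$Nd))
  # without decay the strand count (singles + 2 * duplexes) never decreases
  strands <- c(sum(init$Ns) + 2 * sum(init$Nd))
  s <- strands
  for (i in seq_len(nrow(tr$events))) {
    ch <- tr$events$channel[i]
    s <- s + (ch %in% c("rna_poly", "clay_oligo", "clay_poly"))
  }
  expect_equal(s, sum(tr$final$Ns) + 2 * sum(tr$final$Nd))
  # class-count series sums to K at every step
  expect_equal(unname(rowSums(tr$class_counts)), c(init$K, tr$events$K))
})

test_that("the simulator matches the analytic law of a linear birth process", {
  # constant-similarity landscape, single species pool: pure birth with
  # rate a * K(K-1); transition K -> K+1. Compare the mean time to go from
  # 2 to 12 molecules with the analytic sum of exponential means.
  n <- 2
  ls <- landscape(build_manifold(members = "AA"), k = 0, l = 0, a = 0.5,
                  similarity = "constant", b = 1)
  rates <- reaction_rates(kds = 0, kss = 0)
  init <- population(c("AA", "AA"))
  set.seed(46)
  times <- replicate(300, {
    tr <- simulate_population(ls, init, rates, budget = 10)
    tr$end_time
  })
  analytic <- sum(1 / (0.5 * (2:11) * (2:11 - 1)))
  expect_lt(abs(mean(times) - analytic), 4 * sd(times) / sqrt(length(times)))
})
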