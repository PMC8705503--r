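test_that("volume fraction counts high-fidelity singles and duplexes", {
  R <- c("AAA")
  # 2 molecules in X_R among 8 total
  pop <- population(singles = c("AAA", "GAU", "GAU", "CCC", "GGA", "UCA", "AGA"),
                    duplexes = "AAA")
  expect_equal(volume_fraction(pop, R), 2 / 8)
  expect_equal(volume_fraction(population(c("AAA", "AAA")), R), 1)
  expect_equal(volume_fraction(population(c("GAU", "CCA")), R), 0)
  # a duplex containing the complement of a member also counts
  expect_equal(volume_fraction(population(duplexes = "UUU", n = 3), R), 1)
  expect_error(volume_fraction(population(n = 3), R), "empty")
})

test_that("detectors replay an event log to the definitions", {
  set.seed(51)
  ls <- tiny_landscape(n = 3, terminus = 0.01)
  init <- init_population(3, 10, ls$R, avoid_R = TRUE)
  tr <- simulate_population(ls, init, reaction_rates(), budget = 5000,
                            v = 0.25, seed = 52)
  rec <- hitting_records(tr)
  # replayed records equal the online detections
  for (ev in names(tr$hits)) {
    if (is.na(tr$hits[[ev]])) expect_true(rec[[ev]]$censored)
    else expect_equal(rec[[ev]]$time, tr$hits[[ev]])
  }
  # tau_rep is the time of the first K-increasing event
  first_growth <- tr$events$time[which(tr$events$K > tr$I)[1L]]
  expect_equal(rec$tau_rep$time, first_growth)
  # determinism: replaying twice gives identical records
  rec2 <- hitting_records(tr)
  expect_identical(rec, rec2)
})

test_that("hitting-time ordering tau_R <= tau_min <= tau_v holds on finite triples", {
  set.seed(53)
  ok <- 0L
  for (s in 1:6) {
    ls <- tiny_landscape(n = 3, R_seq = rna_decode(sample.int(64, 1) - 1L, 3),
                         terminus = 0.01)
    init <- init_population(3, 10, ls$R, avoid_R = TRUE)
    tr <- simulate_population(ls, init, reaction_rates(), budget = 5000,
                              v = 0.1, seed = 530 + s)
    rec <- hitting_records(tr)
    if (!rec$tau_R$censored && !rec$tau_min$censored && !rec$tau_v$censored) {
      expect_lte(rec$tau_R$time, rec$tau_min$time)
      expect_lte(rec$tau_min$time, rec$tau_v$time)
      ok <- ok + 1L
    }
    # censored records carry the trajectory end time
    for (r in rec) if (r$censored) expect_equal(r$censor_time, tr$end_time)
  }
  expect_gte(ok, 1L)   # the corpus contains finite triples
})

test_that("tau_min marks the (last) running-minimum of V after tau_R, configurable to first", {
  # hand-built log: manufacture a trajectory object with a known V path
  ls <- tiny_landscape(n = 3, R_seq = "AAA")
  init <- population(c("AAA", "GAU", "GAU", "GAU"))   # V(0) = 1/4, tau_R = 0
  ev <- data.frame(
    time = c(0.1, 0.2, 0.3, 0.4),
    channel = c("clay_oligo", "clay_oligo", "rna_poly", "rna_poly"),
    r1 = NA_integer_, r2 = NA_integer_,
    prod = rna_encode(c("GGA", "CCA", "AAA", "AAA")),
    K = c(5L, 6L, 7L, 8L), V = c(1/5, 1/6, 2/7, 3/8))
  traj <- structure(list(n = 3, I = 4L, events = ev, init = init,
                         end_time = 0.4, R = rna_encode("AAA"), v = NULL),
                    class = "rna_trajectory")
  expect_equal(detect_tau_R(traj)$time, 0)
  # V dips to 1/6 at t = 0.2 then rises: tau_min = 0.2
  expect_equal(detect_tau_min(traj)$time, 0.2)
  expect_equal(detect_tau_v(traj, v = 0.3)$time, 0.4)   # first V >= 0.3 is 3/8
  expect_equal(detect_tau_v(traj, v = 0.25)$time, 0)    # V(0) = 1/4 already
  expect_equal(detect_tau_v(traj, v = 0)$time, 0)
  expect_true(detect_tau_v(traj, v = 0.9)$censored)
  # the running minimum re-attained later: last vs first attainment
  ev2 <- data.frame(
    time = seq(0.1, 0.6, by = 0.1),
    channel = "clay_oligo", r1 = NA_integer_, r2 = NA_integer_,
    prod = rna_encode(c("GGA", "AAA", "CCG", "GCA", "UGC", "CAG")),
    K = 5:10, V = 0)
  ev2$channel[2] <- "rna_poly"
  traj2 <- structure(list(n = 3, I = 4L, events = ev2, init = init,
                          end_time = 0.6, R = rna_encode("AAA"), v = NULL),
                     class = "rna_trajectory")
  # V path: 1/4, 1/5, 2/6, 2/7, 2/8, 2/9, 2/10 -> min 0.2 at t = 0.1 and 0.6
  expect_equal(detect_tau_min(traj2)$time, 0.6)
  expect_equal(detect_tau_min(traj2, first = TRUE)$time, 0.1)
  # all-censored situation: no R member ever
  init3 <- population(c("GAU", "GAU"))
  ev3 <- ev[1:2, ]
  traj3 <- structure(list(n = 3, I = 2L, events = ev3, init = init3,
                          end_time = 0.2, R = rna_encode("AAA"), v = NULL),
                     class = "rna_trajectory")
  expect_true(detect_tau_R(traj3)$censored)
  expect_true(detect_tau_min(traj3)$censored)
})
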