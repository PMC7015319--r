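# Simulation engine: waiting times, reproducibility, analytic limits,
# propensity bookkeeping, exclusion, conservation.

test_that("waiting times are exponential with mean 1/Phi", {
  dts <- draw_waiting_times(1e4, phi = 2, seed = 21)
  se <- stats::sd(dts) / sqrt(length(dts))
  expect_lt(abs(mean(dts) - 0.5), 3 * se)
  # scale invariance: rate 10 halves-of-means etc.
  dts10 <- draw_waiting_times(1e4, phi = 10, seed = 22)
  expect_lt(abs(mean(dts10) - 0.1), 3 * stats::sd(dts10) / sqrt(1e4))
})

test_that("identical seeds give identical trajectories, different seeds differ", {
  sys <- make_toy_system(n_genes = 2, length_aa = 15, n_trnas = 2,
                         n_ribosomes = 3, seed = 1)
  a <- simulate_translation(sys, t_end = 40, seed = 9)
  b <- simulate_translation(sys, t_end = 40, seed = 9)
  expect_identical(a$completions, b$completions)
  expect_identical(a$n_events, b$n_events)
  expect_identical(a$event_counts, b$event_counts)
  expect_identical(a$checkpoints, b$checkpoints)
  c <- simulate_translation(sys, t_end = 40, seed = 10)
  expect_false(identical(a$n_events, c$n_events) &&
               identical(a$completions, c$completions))
  # the engine does not touch R's RNG
  set.seed(1); x <- runif(1)
  simulate_translation(sys, t_end = 1, seed = 3)
  set.seed(1); expect_identical(runif(1), x)
})

test_that("t_end = 0 returns the initial state unchanged", {
  sys <- make_toy_system(seed = 1)
  sim <- simulate_translation(sys, t_end = 0, seed = 1)
  expect_identical(sim$n_events, 0)
  st <- initial_state(sys)
  expect_identical(unname(sim$final_state$pools), as.numeric(st$pools))
  expect_identical(unname(sim$final_state$charged), as.numeric(st$charged))
})

test_that("pure-death extinction time matches the closed-form expectation", {
  n <- 100; k <- 2
  sys <- pure_death_system(n, k)
  st <- pure_death_state(sys, n)
  reps <- 200
  times <- vapply(seq_len(reps), function(i) {
    sim <- simulate_translation(sys, t_end = Inf, seed = 1000 + i,
                                sample_every = 0, state = st)
    expect_identical(sim$status, "deadlock")
    sim$t_final
  }, numeric(1))
  expected <- sum(1 / (k * seq_len(n)))        # sum of stage means
  sd_one <- sqrt(sum(1 / (k * seq_len(n))^2))  # stage variances add
  expect_lt(abs(mean(times) - expected), 3 * sd_one / sqrt(reps))
})

test_that("a single unhindered ribosome approaches the serial-pipeline rate", {
  sys <- serial_system(length_aa = 60, k_slow = 10)
  sim <- simulate_translation(sys, t_end = 400, seed = 31)
  cp <- peptide_elongation_rate(sim)
  expect_lt(abs(cp - serial_expected_cp(sys)) / serial_expected_cp(sys), 0.05)
  # and the limit is set by the slow step: well below it is impossible
  expect_lt(cp, 10)
})

test_that("maintained propensities agree with full recomputation", {
  sys <- make_toy_system(n_genes = 4, length_aa = 25, n_trnas = 3,
                         n_ribosomes = 8, seed = 6)
  sim <- simulate_translation(sys, t_end = 150, seed = 41, check_every = 1000,
                              resync_every = 1e9) # no resync: drift is real
  expect_gt(sim$n_events, 1e4)
  expect_lt(sim$max_phi_rel_dev, 1e-9)
})

test_that("P-site separations never fall below the post-move minimum", {
  sys <- make_toy_system(n_genes = 2, length_aa = 60, n_trnas = 2,
                         n_ribosomes = 12, seed = 7)
  sim <- simulate_translation(sys, t_end = 120, seed = 51,
                              track_min_separation = TRUE)
  expect_gte(sim$min_p_site_separation, 14)
})

test_that("deadlock is reported with the starved channels", {
  # one tRNA species, no way to charge it (no synthetase flux): after the
  # free TC is consumed the cell must halt and name the starved species
  tab <- toy_rate_table()
  tab$rate[tab$reaction == "aminoacylation"] <- 0
  sys <- make_toy_system(n_genes = 1, length_aa = 30, n_trnas = 1,
                         n_ribosomes = 2, trna_per_species = 5,
                         rates = tab, seed = 8)
  sim <- simulate_translation(sys, t_end = 1e4, seed = 61)
  expect_identical(sim$status, "deadlock")
  expect_true(any(grepl("free_TC:t1", sim$starved)))
})

test_that("conservation holds exactly at every checkpoint", {
  sys <- make_toy_system(n_genes = 3, length_aa = 30, n_trnas = 2,
                         n_ribosomes = 6, seed = 9)
  sim <- simulate_translation(sys, t_end = 120, seed = 71, sample_every = 1)
  tf <- sim$totals_factors
  for (cc in colnames(tf)) expect_identical(unname(tf[, cc]),
                                            rep(unname(tf[1, cc]), nrow(tf)))
  tt <- sim$totals_trna
  for (cc in colnames(tt)) expect_identical(unname(tt[, cc]),
                                            rep(unname(tt[1, cc]), nrow(tt)))
  # independent R-side scan of the dumped final state agrees
  rt <- r_species_totals(sim$final_state)
  ft <- sim$final_totals$factors
  expect_identical(rt$total_30S, unname(ft[["total_30S"]]))
  expect_identical(rt$total_50S, unname(ft[["total_50S"]]))
  expect_identical(rt$EfTu, unname(ft[["EfTu"]]))
  expect_identical(rt$EfG, unname(ft[["EfG"]]))
  expect_identical(unname(rt$trna), unname(sim$final_totals$trna))
})

test_that("the naive and tree engines expose the same kinetics", {
  sys <- make_toy_system(n_genes = 3, length_aa = 20, n_trnas = 2,
                         n_ribosomes = 4, seed = 10)
  a <- simulate_translation(sys, t_end = 30, seed = 81)
  b <- simulate_translation(sys, t_end = 30, seed = 81, engine = "naive")
  # same reaction catalogue is reachable in both
  expect_identical(colnames(a$event_counts), colnames(b$event_counts))
  ca <- colSums(a$event_counts) > 0
  cb <- colSums(b$event_counts) > 0
  expect_identical(ca, cb)
})
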