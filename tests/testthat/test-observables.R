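# Observables: elongation rates, state fractions, free-TC ratios, decode
# statistics, spacing.

fake_sim <- function(completions = NULL, checkpoints = NULL, t_final = 100,
                     n_ribosomes = 10, n_mrna = 3, n_nt = 1000,
                     free_tc = NULL, trna_totals = NULL) {
  structure(list(completions = completions, checkpoints = checkpoints,
                 t_final = t_final, n_ribosomes = n_ribosomes,
                 n_mrna = n_mrna, n_nt = n_nt, free_tc = free_tc,
                 trna_totals = trna_totals), class = "translation_sim")
}

test_that("per-protein rates are amino acids over elongation time", {
  cmp <- data.frame(gene = "g", length_aa = 300, t_init = 0,
                    t_elong_begin = 1, t_elong_end = 21, t_release = 22)
  er <- elongation_rates(cmp, window = 1)
  expect_identical(er$rate, 15)           # 300 aa / 20 s
  sim <- fake_sim(completions = cmp, t_final = 22)
  expect_identical(peptide_elongation_rate(sim, tail_fraction = 1), 15)
  # total-dwell denominator includes initiation and termination
  expect_equal(peptide_elongation_rate(sim, tail_fraction = 1,
                                       denominator = "total"), 300 / 22)
  bad <- cmp; bad$t_elong_end <- bad$t_elong_begin
  expect_error(elongation_rates(bad, window = 1), "zero-duration")
})

test_that("the running mean uses a trailing window of completions", {
  n <- 2500
  cmp <- data.frame(gene = "g", length_aa = 100, t_init = 0,
                    t_elong_begin = 0, t_elong_end = seq_len(n),
                    t_release = seq_len(n) + 0.1)
  cmp$t_elong_begin <- cmp$t_elong_end - 100 / seq(8, 12, length.out = n)
  er <- elongation_rates(cmp, window = 1000)
  expect_true(all(is.na(er$running[1:999])))
  expect_equal(er$running[1000], mean(er$rate[1:1000]))
  expect_equal(er$running[n], mean(er$rate[(n - 999):n]))
})

test_that("state fractions are percentages of total ribosomes", {
  ck <- data.frame(time = c(60, 80, 100), free_50S = 6, free_30S_PIC = 6,
                   initiating = 0, elongating = 3, terminating = 1,
                   stalled = 1, bound = 4)
  sim <- fake_sim(checkpoints = ck, t_final = 100, n_ribosomes = 10)
  fr <- state_fractions(sim, tail_fraction = 0.5)
  expect_identical(fr$pct_elongating, 30)
  expect_identical(fr$pct_terminating, 10)
  expect_identical(fr$pct_free_50S, 60)
  expect_identical(fr$beta_r, 40)
  expect_identical(fr$pct_stalled, 10)
  expect_equal(fr$pct_stalled_of_elongating, 100 / 3)

  # all subunits free
  ck0 <- data.frame(time = 100, free_50S = 10, free_30S_PIC = 10,
                    initiating = 0, elongating = 0, terminating = 0,
                    stalled = 0, bound = 0)
  fr0 <- state_fractions(fake_sim(checkpoints = ck0, n_ribosomes = 10))
  expect_identical(fr0$pct_free_50S, 100)
  expect_identical(fr0$pct_elongating + fr0$pct_initiating +
                   fr0$pct_terminating, 0)
})

test_that("free-TC fractions average the trailing window per species", {
  m <- cbind(tA = c(10, 10, 20, 20), tB = c(0, 0, 40, 40))
  sim <- fake_sim(checkpoints = data.frame(time = c(10, 50, 150, 200)),
                  t_final = 200, free_tc = m,
                  trna_totals = c(tA = 40, tB = 40))
  fr <- free_tc_fractions(sim, window = 100, sort_output = FALSE)
  expect_identical(fr$fraction, c(0.5, 1.0)) # rows at t = 150, 200 only
  # everything parked in free TC gives fraction one
  expect_identical(fr$fraction[2], 1.0)
  # sorted presentation ascends
  fs <- free_tc_fractions(sim, window = 100)
  expect_identical(fs$trna, c("tA", "tB"))
})

test_that("free-TC stationary fraction matches the birth-death solution", {
  # one tRNA species cycling between free TC and the rest of the cell:
  # per-molecule entry rate a (TC formation at fixed EF-Tu:GTP), exit rate b
  # (consumption by a ribosome that is essentially always waiting); the
  # two-state stationary occupancy of TC is a / (a + b).
  tab <- reaction_catalogue()
  tab$rate <- ifelse(tab$order == 2L, 1e10, 2000)
  tab$rate[tab$reaction == "tc_rejection"] <- 0
  tab$rate[tab$reaction == "aminoacylation"] <- 2000
  conv <- 6.02214076e23 * 1e-15
  eftu <- 10000
  a <- 2; b <- 1
  tab$rate[tab$reaction == "tc_formation"] <- a / eftu * conv
  tab$rate[tab$reaction == "tc_binding"] <- b * conv
  sys <- make_toy_system(n_genes = 1, length_aa = 50, n_trnas = 1,
                         n_ribosomes = 1, trna_per_species = 50,
                         factors = c(EfTu = eftu, EfTs = eftu, EfG = 1000,
                                     RF1 = 100, RF2 = 100, RF3 = 100,
                                     RRF = 100),
                         rates = rate_table(tab), seed = 12)
  sim <- simulate_translation(sys, t_end = 400, seed = 91)
  fr <- free_tc_fractions(sim, window = 350)
  expect_lt(abs(fr$fraction - a / (a + b)), 0.05)
})

test_that("decode statistics aggregate waits and stalls per codon", {
  log <- data.frame(codon = c("AAA", "AAA", "AAA", "GGG"),
                    wait = c(1, 2, 3, 10), stalled = c(FALSE, TRUE, FALSE, TRUE))
  cs <- codon_decode_stats(log)
  expect_identical(cs$mean_wait[cs$codon == "AAA"], 2)
  expect_identical(cs$n_events[cs$codon == "AAA"], 3)
  expect_equal(cs$stall_frequency[cs$codon == "AAA"], 1 / 3)
})

# decode events of peptides still on the ribosomes at t_end (phases after
# peptide release are excluded: their decodes are already in `completions`)
sum_partial_decodes <- function(sim) {
  ribs <- do.call(rbind, sim$final_state$ribosomes)
  if (is.null(ribs) || !nrow(ribs)) return(0)
  post <- ribs$phase %in% c("released", "post_termination", "rrf_bound")
  ribs <- ribs[!post, , drop = FALSE]
  if (!nrow(ribs)) return(0)
  # a ribosome at P site p has decoded p-1 codons, plus one more if the
  # peptide bond of the current cycle is already formed
  sum(ribs$p_site - 1 +
        as.integer(ribs$phase %in% c("pre_translocation", "efg_bound")))
}

test_that("a starved codon shows far more stalling than a supplied one", {
  # two species: t2 has two copies with slow recharging, so its codon
  # starves while t1's codon stays well supplied. With one ribosome the
  # cell cannot deadlock: a starved copy always cycles back eventually.
  tab <- toy_rate_table(k_slow = 50)
  tab$rate[tab$reaction == "aminoacylation"] <- 2
  sys <- make_toy_system(n_genes = 1, length_aa = 30, n_trnas = 2,
                         n_ribosomes = 1, trna_per_species = 200,
                         factors = c(EfTu = 5000), rates = rate_table(tab),
                         seed = 13)
  st <- initial_state(sys)
  st$charged[] <- c(200L, 2L)
  sim <- simulate_translation(sys, t_end = 100, seed = 92, state = st)
  expect_identical(sim$status, "completed")
  cs <- codon_decode_stats(sim)
  cod <- vapply(c("t1", "t2"), function(t)
    cognate_codons(sys$map, t), character(1))
  i1 <- match(cod[1], cs$codon); i2 <- match(cod[2], cs$codon)
  expect_gt(cs$mean_wait[i2], cs$mean_wait[i1])
  expect_gt(cs$stall_frequency[i2], 5 * max(cs$stall_frequency[i1], 0.01))
  # ledger identity: decode events = peptide bonds formed
  expect_identical(sum(sim$codon_stats$n_events),
                   sum(sim$completions$length_aa) +
                   sum_partial_decodes(sim))
})

test_that("spacing follows d_r = N_nt / (beta_r N_50) with a physical floor", {
  sp <- ribosome_spacing(1000, 0.5, 20)
  expect_identical(sp$d_r, 100)
  expect_identical(sp$rho, 0.01)
  expect_warning(ribosome_spacing(300, 1, 300), "impossible")
  expect_identical(suppressWarnings(ribosome_spacing(300, 1, 300))$d_r, 1)
  expect_error(ribosome_spacing(-1, 0.5, 10))
  expect_error(ribosome_spacing(100, 1.5, 10), "fraction")
})

test_that("replicate summaries report mean and dispersion", {
  sys <- make_toy_system(n_genes = 2, length_aa = 15, n_trnas = 2,
                         n_ribosomes = 3, seed = 14)
  sims <- lapply(c(101, 102, 103), function(s)
    simulate_translation(sys, t_end = 60, seed = s))
  sm <- summarize_runs(sims)
  expect_identical(unique(sm$n), 3L)
  cp_row <- sm[sm$quantity == "c_p", ]
  cps <- vapply(sims, peptide_elongation_rate, numeric(1))
  expect_equal(cp_row$mean, mean(cps))
  expect_equal(cp_row$sd, stats::sd(cps))
})
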