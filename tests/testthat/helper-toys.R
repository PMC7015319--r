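# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# A single-ribosome, single-mRNA cell with saturating pools, used for
# serial-pipeline analytic limits.
serial_system <- function(length_aa = 60, k_slow = 10, k_fast = 1000,
                          seed = 2) {
  make_toy_system(n_genes = 1, length_aa = length_aa, n_trnas = 1,
                  n_ribosomes = 1, trna_per_species = 500,
                  factors = c(EfTu = 5000, EfTs = 5000, EfG = 5000,
                              RF1 = 500, RF2 = 500, RF3 = 500, RRF = 500),
                  rates = toy_rate_table(k_slow = k_slow, k_fast = k_fast),
                  seed = seed)
}

# Expected steady per-codon elongation time of the serial pipeline, from the
# same rate table and pools the system was built with (independent closed
# form: sum of exponential stage means).
serial_expected_cp <- function(system) {
  k <- rate_constants(system$rates, system$volume)
  ftc <- sum(system$pools$trna$total) # everything cycles through free TC fast
  per_codon <-
    1 / (k[["tc_binding"]] * ftc * 0.9) + # ~10% of tRNA transiently elsewhere
    1 / k[["gtpase_hydrolysis"]] +
    1 / k[["accommodation"]] +
    1 / k[["peptidyl_transfer"]] +
    1 / (k[["efg_binding"]] * system$pools$pools[["EfG_GTP"]]) +
    1 / k[["translocation"]]
  1 / per_codon
}

# Pure-death fixture: n deacylated tRNAs charging at rate k_aa, nothing else
# possible (no ribosomes, no EF-Tu). Trajectory ends (Phi = 0) at the
# extinction time of the deacylated pool.
pure_death_system <- function(n_molecules = 100, k_aa = 2) {
  tab <- toy_rate_table()
  tab$rate[tab$reaction == "aminoacylation"] <- k_aa
  sys <- make_toy_system(n_genes = 1, length_aa = 5, n_trnas = 1,
                         n_ribosomes = 0, trna_per_species = n_molecules,
                         factors = c(EfTu = 0, EfTs = 0, EfG = 0,
                                     RF1 = 0, RF2 = 0, RF3 = 0, RRF = 0),
                         rates = tab, seed = 5)
  sys
}

pure_death_state <- function(system, n_molecules = 100) {
  st <- initial_state(system)
  st$charged[] <- 0L
  st$deacylated[] <- n_molecules
  st$free_tc[] <- 0L
  st
}

# Independent R-side conservation scan over a dumped engine state.
r_species_totals <- function(state) {
  p <- state$pools
  ribs <- do.call(rbind, state$ribosomes)
  n_onrib <- function(x) if (is.null(ribs) || !nrow(ribs)) 0L else x
  on_30S <- if (is.null(ribs)) 0L else nrow(ribs)
  on_50S <- if (is.null(ribs)) 0L else sum(ribs$phase != "init_30S")
  on_eftu <- if (is.null(ribs)) 0L else
    sum(ribs$phase %in% c("tc_bound", "accommodating"))
  on_efg <- if (is.null(ribs)) 0L else sum(ribs$phase == "efg_bound")
  on_rf1 <- if (is.null(ribs)) 0L else sum(ribs$rf == 1)
  on_rf2 <- if (is.null(ribs)) 0L else sum(ribs$rf == 2)
  on_rrf <- if (is.null(ribs)) 0L else sum(ribs$phase == "rrf_bound")
  trna_on <- table(c(ribs$a_trna[!is.na(ribs$a_trna)],
                     ribs$p_trna[!is.na(ribs$p_trna)]))
  trna_on <- trna_on[names(trna_on) != "initiator"]
  tr <- state$deacylated + state$charged + state$free_tc
  tr[names(trna_on)] <- tr[names(trna_on)] + as.integer(trna_on)
  list(
    total_30S = unname(p[["free_30S_PIC"]] + on_30S),
    total_50S = unname(p[["free_50S"]] + on_50S),
    EfTu = unname(p[["EfTu_GTP"]] + p[["EfTu_GDP"]] + p[["EfTu_Ts"]] +
                  sum(state$free_tc) + on_eftu),
    EfTs = unname(p[["EfTs_free"]] + p[["EfTu_Ts"]]),
    EfG = unname(p[["EfG_GTP"]] + p[["EfG_GDP"]] + on_efg),
    RF1 = unname(p[["RF1"]] + on_rf1),
    RF2 = unname(p[["RF2"]] + on_rf2),
    RF3 = unname(p[["RF3_GTP"]] + p[["RF3_GDP"]]),
    RRF = unname(p[["RRF"]] + on_rrf),
    trna = tr
  )
}

# Hand-built state helper: one mRNA system with ribosomes placed explicitly.
place_ribosomes <- function(system, ribs, mrna = 1L) {
  st <- initial_state(system)
  st$ribosomes[[mrna]] <- ribs
  st
}
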