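# Reaction catalogue: enumeration, propensities, stoichiometry, footprint.

toy2 <- function(...) make_toy_system(n_genes = 1, length_aa = 40,
                                      n_trnas = 2, n_ribosomes = 5, seed = 3,
                                      ...)

test_that("an empty mRNA with ample pools offers exactly one entry point", {
  sys <- toy2()
  rx <- enumerate_reactions(sys)
  local <- rx[rx$mrna == 1, ]
  expect_identical(local$reaction, "pic_binding")
  # global side: charging/TC formation for the charged pool
  expect_true(all(rx$reaction[rx$mrna == 0] %in%
                  c("aminoacylation", "tc_formation", "efts_binding",
                    "efts_exchange", "efg_exchange", "rf3_exchange")))
})

test_that("TC binding is only offered for cognate species with free TC", {
  sys <- toy2()
  st <- place_ribosomes(sys, data.frame(
    phase = "await_tc", p_site = 5, a_trna = NA, p_trna = "t1", rf = 0L))
  # A-site codon is codon 6 of the sampled ORF; find its cognate species
  cods <- strsplit(sys$transcriptome$genes$sequence[1], " ")[[1]]
  asite <- cods[6]
  cognate <- sys$map$trna[sys$map$codon == asite]

  st$free_tc[] <- 10L
  rx <- enumerate_reactions(sys, st)
  tc <- rx[rx$reaction == "tc_binding", ]
  expect_identical(sort(tc$trna), sort(cognate))

  st$free_tc[cognate] <- 0L
  rx0 <- enumerate_reactions(sys, st)
  expect_false(any(rx0$reaction == "tc_binding"))
})

test_that("bimolecular propensities follow k * n1 * n2 / (N_A v)", {
  map <- decode_map(data.frame(trna = c("Lys", "Lys"), codon = c("AAA", "AAG")))
  tab <- default_rate_table()
  tab$rate[tab$reaction == "tc_formation"] <- 1e8
  tx <- transcriptome(data.frame(gene_id = "g", length_aa = 2, copies = 1,
                                 sequence = "AUG AAA AAG UAA"))
  pools <- structure(list(
    pools = c(free_30S_PIC = 0L, free_50S = 0L, EfTu_GTP = 100L,
              EfTu_GDP = 0L, EfTu_Ts = 0L, EfTs_free = 0L, EfG_GTP = 0L,
              EfG_GDP = 0L, RF1 = 0L, RF2 = 0L, RF3_GTP = 0L, RF3_GDP = 0L,
              RRF = 0L),
    trna = data.frame(trna = "Lys", total = 10L, deacylated = 0L,
                      charged = 10L, free_tc = 0L)), class = "species_pools")
  sys <- translation_system(tx, pools, rate_table(tab), map, volume = 1.0)
  rx <- enumerate_reactions(sys)
  tcf <- rx[rx$reaction == "tc_formation", ]
  expect_equal(tcf$propensity,
               10 * 100 * 1e8 / (6.02214076e23 * 1e-15), tolerance = 1e-12)
})

test_that("pool-level reactions vanish with their reactants", {
  sys <- toy2()
  st <- initial_state(sys)
  # no deacylated tRNA of t1 -> no charging event for it
  st$deacylated[] <- c(0L, 4L)
  st$charged[] <- 0L
  st$free_tc[] <- 0L
  rx <- enumerate_reactions(sys, st)
  aa <- rx[rx$reaction == "aminoacylation", ]
  expect_identical(aa$trna, "t2")
  # all EF-Tu in GTP form -> no Ts-mediated exchange steps
  expect_false(any(rx$reaction %in% c("efts_binding", "efts_exchange")))
})

test_that("firing applies stoichiometry atomically and conserves totals", {
  sys <- toy2()
  st <- initial_state(sys)
  before <- species_totals(sys, st)
  out <- fire_reaction(sys, st, "tc_formation", mrna = 0, trna = "t1")
  expect_equal(out$pools[["EfTu_GTP"]], st$pools[["EfTu_GTP"]] - 1)
  expect_equal(out$charged[["t1"]], st$charged[["t1"]] - 1)
  expect_equal(out$free_tc[["t1"]], st$free_tc[["t1"]] + 1)
  expect_equal(out$charged[["t2"]], st$charged[["t2"]])
  expect_equal(out$totals$factors, before$factors)
  expect_equal(out$totals$trna, before$trna)
})

test_that("a full elongation cycle has the textbook net balance", {
  # ORF AUG c c stop with a previously decoded tRNA in the P site: one cycle
  # consumes a charged tRNA (via TC formation) and one EF-Tu:GTP + EF-G:GTP,
  # and releases one deacylated tRNA, one EF-Tu:GDP and one EF-G:GDP.
  sys <- make_toy_system(n_genes = 1, length_aa = 2, n_trnas = 1,
                         n_ribosomes = 2, seed = 4)
  st <- place_ribosomes(sys, data.frame(
    phase = "await_tc", p_site = 2, a_trna = NA, p_trna = "t1", rf = 0L))
  st$charged[] <- 5L; st$deacylated[] <- 0L; st$free_tc[] <- 0L
  s0 <- st
  seqrx <- list(
    list("tc_formation", 0L, NA, "t1"),
    list("tc_binding", 1L, 2L, "t1"),
    list("gtpase_hydrolysis", 1L, 2L, ""),
    list("accommodation", 1L, 2L, ""),
    list("peptidyl_transfer", 1L, 2L, ""),
    list("efg_binding", 1L, 2L, ""),
    list("translocation", 1L, 2L, ""))
  for (r in seqrx) {
    out <- fire_reaction(sys, st, r[[1]], mrna = r[[2]], p_site = r[[3]],
                         trna = r[[4]])
    st <- out[c("pools", "deacylated", "charged", "free_tc", "ribosomes")]
  }
  expect_equal(st$charged[["t1"]], s0$charged[["t1"]] - 1)
  expect_equal(st$deacylated[["t1"]], s0$deacylated[["t1"]] + 1)
  expect_equal(st$free_tc[["t1"]], s0$free_tc[["t1"]])
  expect_equal(st$pools[["EfTu_GTP"]], s0$pools[["EfTu_GTP"]] - 1)
  expect_equal(st$pools[["EfTu_GDP"]], s0$pools[["EfTu_GDP"]] + 1)
  expect_equal(st$pools[["EfG_GTP"]], s0$pools[["EfG_GTP"]] - 1)
  expect_equal(st$pools[["EfG_GDP"]], s0$pools[["EfG_GDP"]] + 1)
  # the ribosome moved to the stop codon and awaits a release factor
  expect_identical(st$ribosomes[[1]]$phase, "await_rf")
  expect_identical(st$ribosomes[[1]]$p_site, 3L)
})

test_that("termination and recycling empty a single-ribosome mRNA", {
  sys <- make_toy_system(n_genes = 1, length_aa = 2, n_trnas = 1,
                         n_ribosomes = 2, seed = 4)
  st <- place_ribosomes(sys, data.frame(
    phase = "await_rf", p_site = 3, a_trna = NA, p_trna = "t1", rf = 0L))
  s0 <- st
  released <- 0L
  for (r in list(list("rf1_binding"), list("peptide_release"),
                 list("rf_dissociation"), list("rrf_binding"),
                 list("recycling"))) {
    out <- fire_reaction(sys, st, r[[1]], mrna = 1L, p_site = 3L)
    if (r[[1]] == "peptide_release") released <- out$completions
    st <- out[c("pools", "deacylated", "charged", "free_tc", "ribosomes")]
  }
  expect_identical(nrow(st$ribosomes[[1]]), 0L)
  expect_equal(st$pools[["free_50S"]], s0$pools[["free_50S"]] + 1)
  expect_equal(st$pools[["free_30S_PIC"]], s0$pools[["free_30S_PIC"]] + 1)
  expect_equal(st$pools[["RF1"]], s0$pools[["RF1"]])   # returned
  expect_equal(st$pools[["RRF"]], s0$pools[["RRF"]])   # returned
  expect_equal(st$pools[["RF3_GDP"]], s0$pools[["RF3_GDP"]] + 1)
  expect_equal(st$deacylated[["t1"]], s0$deacylated[["t1"]] + 1)
  expect_identical(released, 1L)
})

test_that("stop codon identity selects the release factor class", {
  mk <- function(stop) {
    tx <- transcriptome(data.frame(gene_id = "g", length_aa = 1, copies = 1,
                                   sequence = paste("AUG AAA", stop)))
    map <- decode_map(data.frame(trna = "t1", codon = "AAA"))
    pools <- structure(list(
      pools = c(free_30S_PIC = 1L, free_50S = 1L, EfTu_GTP = 5L,
                EfTu_GDP = 0L, EfTu_Ts = 0L, EfTs_free = 5L, EfG_GTP = 5L,
                EfG_GDP = 0L, RF1 = 3L, RF2 = 3L, RF3_GTP = 3L, RF3_GDP = 0L,
                RRF = 3L),
      trna = data.frame(trna = "t1", total = 5L, deacylated = 0L,
                        charged = 5L, free_tc = 0L)), class = "species_pools")
    translation_system(tx, pools, toy_rate_table(), map)
  }
  rf_offered <- function(stop) {
    sys <- mk(stop)
    st <- place_ribosomes(sys, data.frame(
      phase = "await_rf", p_site = 2, a_trna = NA, p_trna = "t1", rf = 0L))
    rx <- enumerate_reactions(sys, st)
    sort(rx$reaction[rx$reaction %in% c("rf1_binding", "rf2_binding")])
  }
  expect_identical(rf_offered("UAA"), c("rf1_binding", "rf2_binding"))
  expect_identical(rf_offered("UAG"), "rf1_binding")
  expect_identical(rf_offered("UGA"), "rf2_binding")
})

test_that("the extended footprint blocks translocation below 15 codons", {
  # pure arithmetic rule
  expect_false(is_blocked(10, 25)) # separation 15: free
  expect_true(is_blocked(10, 24))  # separation 14: blocked
  expect_true(initiation_blocked(15))
  expect_false(initiation_blocked(16))

  sys <- toy2()
  place2 <- function(p, q) place_ribosomes(sys, data.frame(
    phase = c("efg_bound", "await_tc"), p_site = c(p, q),
    a_trna = NA, p_trna = "t1", rf = 0L))
  rx14 <- enumerate_reactions(sys, place2(10, 24))
  expect_false(any(rx14$reaction == "translocation"))
  rx15 <- enumerate_reactions(sys, place2(10, 25))
  expect_identical(rx15$p_site[rx15$reaction == "translocation"], 10L)

  # a single ribosome is never blocked
  solo <- place_ribosomes(sys, data.frame(
    phase = "efg_bound", p_site = 20, a_trna = NA, p_trna = "t1", rf = 0L))
  rxs <- enumerate_reactions(sys, solo)
  expect_true(any(rxs$reaction == "translocation"))

  # initiation occluded while the 5'-most P site is within the footprint
  occl <- place_ribosomes(sys, data.frame(
    phase = "await_tc", p_site = 15, a_trna = NA, p_trna = "t1", rf = 0L))
  expect_false(any(enumerate_reactions(sys, occl)$reaction == "pic_binding"))
  free <- place_ribosomes(sys, data.frame(
    phase = "await_tc", p_site = 16, a_trna = NA, p_trna = "t1", rf = 0L))
  expect_true(any(enumerate_reactions(sys, free)$reaction == "pic_binding"))
})

test_that("each ribosome phase offers only its own forward reactions", {
  sys <- toy2()
  offered <- function(phase, p = 20) {
    st <- place_ribosomes(sys, data.frame(
      phase = phase, p_site = p, a_trna = if (phase %in%
        c("tc_bound", "accommodating", "accommodated", "pre_translocation",
          "efg_bound")) "t1" else NA,
      p_trna = "t1", rf = if (phase %in% c("rf_bound", "released")) 1L else 0L))
    rx <- enumerate_reactions(sys, st)
    sort(unique(rx$reaction[rx$mrna == 1 & !is.na(rx$p_site)]))
  }
  expect_identical(offered("init_30S", 1), "subunit_joining")
  expect_identical(offered("tc_bound"), "gtpase_hydrolysis")
  expect_identical(offered("accommodating"), "accommodation") # rejection off
  expect_identical(offered("accommodated"), "peptidyl_transfer")
  expect_identical(offered("pre_translocation"), "efg_binding")
  expect_identical(offered("efg_bound"), "translocation")
  expect_identical(offered("rf_bound", 41), "peptide_release")
  expect_identical(offered("released", 41), "rf_dissociation")
  expect_identical(offered("post_termination", 41), "rrf_binding")
  expect_identical(offered("rrf_bound", 41), "recycling")
})

test_that("malformed inputs are rejected with informative errors", {
  sys <- toy2()
  expect_error(fire_reaction(sys, NULL, "tc_binding", mrna = 1),
               "not currently fireable")
  tx_bad <- data.frame(gene_id = "g", length_aa = 1, copies = 1,
                       sequence = "AUG UAA UAA")
  expect_error(transcriptome(tx_bad), "internal stop")
  expect_error(codon_code("XYZ"), "unknown codon")
  tab <- default_rate_table()
  expect_error(rate_table(tab[-3, ]), "missing rate entry")
})
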