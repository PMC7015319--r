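# Transcriptome construction: usage arithmetic, the matching solver, codon
# sampling, copy numbers, the builder, FASTA round-trip.

test_that("tRNA counts split equally over cognate codons", {
  m <- decode_map(data.frame(trna = c("Lys", "Lys"), codon = c("AAA", "AAG")))
  raw <- codon_usage_from_trnas(c(Lys = 4360), m, normalize = FALSE)
  expect_identical(raw[["AAA"]], 2180)
  expect_identical(raw[["AAG"]], 2180)

  # single species, single codon: frequency one
  m1 <- decode_map(data.frame(trna = "X", codon = "GGG"))
  expect_identical(codon_usage_from_trnas(c(X = 7), m1)[["GGG"]], 1)

  # {X:100 -> {A,B}, Y:300 -> {B}} -> raw A=50, B=350; freqs 0.125, 0.875
  m2 <- decode_map(data.frame(trna = c("X", "X", "Y"),
                              codon = c("AAA", "GGG", "GGG")))
  f <- codon_usage_from_trnas(c(X = 100, Y = 300), m2)
  expect_identical(unname(f[c("AAA", "GGG")]), c(0.125, 0.875))

  expect_warning(codon_usage_from_trnas(c(X = 0, Y = 10), m2), "unusable")
})

test_that("the matching solver inverts usage up to apportionment degeneracy", {
  # one-to-one decode map: counts proportional to frequencies exactly
  m <- decode_map(data.frame(trna = c("a", "b", "c"),
                             codon = c("AAA", "GGG", "CCC")))
  f <- c(AAA = 0.5, GGG = 0.3, CCC = 0.2)
  sol <- trnas_from_codon_usage(f, m, total_trna = 1000)
  expect_identical(unname(sol$counts[c("a", "b", "c")]), c(500L, 300L, 200L))
  expect_true(sol$feasible)
  expect_false(sol$degenerate)

  # shared codon: a feasible split is found and flagged as degenerate
  m2 <- decode_map(data.frame(trna = c("X", "X", "Y"),
                              codon = c("AAA", "GGG", "GGG")))
  f2 <- c(AAA = 0.25, GGG = 0.75)
  sol2 <- trnas_from_codon_usage(f2, m2, total_trna = 400)
  expect_true(sol2$feasible)
  expect_true(sol2$degenerate)
  expect_lt(max(abs(sol2$achieved_usage - f2)), 1e-6)

  # round-trip on the full 42-species map
  map <- ecoli_trna_map()
  counts <- trna_counts_theoretical("1.07")
  usage <- codon_usage_from_trnas(counts, map)
  back <- trnas_from_codon_usage(usage, map, total_trna = sum(counts))
  expect_true(back$feasible)
  re_usage <- codon_usage_from_trnas(back$counts, map)
  expect_lt(max(abs(re_usage[names(usage)] - usage)), 1e-5)

  # weight on an undecodable codon is an explicit error
  expect_error(trnas_from_codon_usage(c(AAA = 0.5, UUU = 0.5), m2), "no tRNA")
})

test_that("sampled genes have the requested frame and converge in usage", {
  f <- c(AAA = 0.6, GGG = 0.3, CCC = 0.1)
  set.seed(5)
  g <- sample_gene_codons(50, f)
  expect_identical(length(g), 52L)  # start + 50 + stop; 3*(L+2) nt
  expect_identical(g[1], "AUG")
  expect_true(g[52] %in% stop_codons())

  # degenerate frequency vector: homopolymeric ORF
  h <- sample_gene_codons(10, c(GGG = 1), stop_codon = "UAA")
  expect_identical(h, c("AUG", rep("GGG", 10), "UAA"))

  # multinomial convergence at n = 1e6 draws: max deviation < 0.003
  set.seed(6)
  big <- sample_gene_codons(1e6, f, stop_codon = "UAA")
  emp <- table(big[2:(length(big) - 1L)]) / 1e6
  expect_lt(max(abs(emp[names(f)] - f)), 0.003)
})

test_that("copy numbers follow the three-category expression mixture", {
  set.seed(7)
  hi <- sample_copy_number(2e4, category = "high")
  expect_true(all(hi$k >= 1))
  # zero-truncated Poisson(6.8) mean = lambda / (1 - exp(-lambda))
  mu_hi <- 6.8 / (1 - exp(-6.8))
  expect_lt(abs(mean(hi$k) - mu_hi), 3 * stats::sd(hi$k) / sqrt(nrow(hi)))

  lo <- sample_copy_number(2e4, category = "low")
  expect_true(all(lo$k >= 1))
  # zero-truncated geometric p(k) = (1-l)^k l: mean = 1/l
  expect_lt(abs(mean(lo$k) - 1 / 0.93), 3 * stats::sd(lo$k) / sqrt(nrow(lo)))

  mix <- sample_copy_number(5e4)
  frq <- table(mix$category)[c("high", "intermediate", "low")] / nrow(mix)
  p0 <- c(0.05, 0.35, 0.60)
  for (i in 1:3)
    expect_lt(abs(frq[i] - p0[i]), 3 * sqrt(p0[i] * (1 - p0[i]) / nrow(mix)))

  # untruncated draws may include zero
  set.seed(8)
  raw <- sample_copy_number(2e3, category = "low", zero_truncate = FALSE)
  expect_true(any(raw$k == 0))
})

test_that("the builder crosses its stopping target and respects windows", {
  lens <- make_synthetic_gene_lengths(200, meanlog = log(100), sdlog = 0.4,
                                      seed = 11)
  f <- c(AAA = 0.5, GGG = 0.5)

  tx1 <- build_transcriptome(lens, f, target_n = 1, seed = 12)
  expect_identical(nrow(tx1$genes), 1L)

  tx <- build_transcriptome(lens, f, target_nt = 5e4, seed = 13)
  s <- transcriptome_size(tx)
  expect_gte(s$n_nt, 5e4)
  # overshoot bounded by one gene's worth of copies
  g_last <- tx$genes[nrow(tx$genes), ]
  expect_lt(s$n_nt - g_last$copies * 3 * (g_last$length_aa + 2), 5e4)
  # bookkeeping equals recount from sequences
  ncod <- vapply(strsplit(tx$genes$sequence, " "), length, integer(1))
  expect_identical(s$n_nt, sum(3L * ncod * tx$genes$copies))

  txw <- build_transcriptome(lens, f, target_n = 10,
                             length_window = c(600, 900), replace = TRUE,
                             seed = 14)
  nt_per <- 3 * (txw$genes$length_aa + 2)
  expect_true(all(nt_per >= 600 & nt_per <= 900))

  expect_error(build_transcriptome(lens, f, target_n = 5,
                                   length_window = c(1, 2)), "window")
  # deterministic under seed
  tx2 <- build_transcriptome(lens, f, target_nt = 5e4, seed = 13)
  expect_identical(tx$genes, tx2$genes)
})

test_that("a mismatch rebuild preserves genes, lengths and copy numbers", {
  lens <- make_synthetic_gene_lengths(50, meanlog = log(80), seed = 21)
  f1 <- c(AAA = 0.7, GGG = 0.2, CCC = 0.1)
  f2 <- c(AAA = 0.1, GGG = 0.2, CCC = 0.7)
  tx <- build_transcriptome(lens, f1, target_n = 30, replace = TRUE, seed = 22)
  tx2 <- rebuild_with_usage(tx, f2, seed = 23)
  expect_identical(tx2$genes$gene_id, tx$genes$gene_id)
  expect_identical(tx2$genes$length_aa, tx$genes$length_aa)
  expect_identical(tx2$genes$copies, tx$genes$copies)
  expect_identical(transcriptome_size(tx2)$n_nt, transcriptome_size(tx)$n_nt)
  # and actually shifts the codon usage toward the new target
  u2 <- transcriptome_codon_usage(tx2)
  expect_gt(u2[["CCC"]], 0.5)
})

test_that("FASTA + copy-number TSV round-trip is lossless", {
  lens <- make_synthetic_gene_lengths(20, meanlog = log(50), seed = 31)
  tx <- build_transcriptome(lens, c(AAA = 0.5, GGG = 0.5), target_n = 10,
                            replace = TRUE, seed = 32)
  fa <- tempfile(fileext = ".fasta"); ks <- tempfile(fileext = ".tsv")
  write_transcriptome(tx, fa, ks)
  tx2 <- read_transcriptome(fa, ks)
  expect_identical(tx2$genes, tx$genes)
  unlink(c(fa, ks))
})
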