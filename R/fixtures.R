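#' Synthetic gene-length lists
#'
#' Reproducible log-normal ORF lengths (in amino acids) standing in for a
#' proteome-derived length list. The default moments give a right-skewed
#' distribution with a mean around 280 aa, the familiar shape of bacterial
#' protein lengths; desk-scale cells use a smaller mean.
#'
#' @param n number of genes.
#' @param meanlog,sdlog log-normal parameters of the length distribution.
#' @param min_aa floor applied after rounding.
#' @param seed optional integer seed (local to this call).
#' @return Data frame `gene_id`, `length_aa`.
#' @export
make_synthetic_gene_lengths <- function(n, meanlog = log(280), sdlog = 0.45,
                                        min_aa = 10L, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  len <- pmax(as.integer(round(stats::rlnorm(n, meanlog, sdlog))), min_aa)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), length_aa = len,
             stringsAsFactors = FALSE)
}

#' Toy rate table
#'
#' Round-number kinetics for analytic-limit tests: every first-order
#' sub-step runs at `k_fast` except one designated rate-limiting step at
#' `k_slow`, and second-order rates are large enough that, at toy pool
#' sizes, binding steps are far from limiting. With a single slow step the
#' serial elongation cycle approaches `k_slow` aa/s per unhindered
#' ribosome.
#'
#' @param k_slow rate of the limiting step (s^-1).
#' @param k_fast rate of every other first-order step (s^-1).
#' @param k_bi second-order rate (M^-1 s^-1) for all binding steps.
#' @param limiting name of the rate-limiting first-order reaction.
#' @export
toy_rate_table <- function(k_slow = 10, k_fast = 1000, k_bi = 1e10,
                           limiting = "translocation") {
  tab <- reaction_catalogue()
  tab$rate <- ifelse(tab$order == 2L, k_bi, k_fast)
  tab$rate[tab$reaction == "tc_rejection"] <- 0
  stopifnot(limiting %in% tab$reaction[tab$order == 1L])
  tab$rate[tab$reaction == limiting] <- k_slow
  rate_table(tab)
}

#' Deterministic toy translation systems
#'
#' A complete, runnable micro-cell for tests and exploration: a few short
#' genes over a restricted codon alphabet, a handful of tRNA species (one
#' per codon-block), a small ribosome pool and ample factors, with round
#' toy kinetics. Deterministic under `seed`.
#'
#' @param n_genes number of genes (one mRNA copy each by default).
#' @param length_aa sense codons per ORF (single number or per-gene vector).
#' @param n_trnas number of tRNA species; species `t1..tn` decode disjoint
#'   sense codons.
#' @param n_ribosomes ribosome count (30S = 50S).
#' @param copies mRNA copies per gene.
#' @param trna_per_species tRNA copy number per species.
#' @param factors named overrides for factor pool sizes (defaults: EF-Tu
#'   4x ribosomes, EF-Ts/EF-G 2x, RFs/RRF 1x).
#' @param rates a rate table, default [toy_rate_table()].
#' @param instant_tc bypass TC formation (tRNAs start in free TC).
#' @param seed integer seed for the codon sampling.
#' @return A [translation_system()].
#' @export
make_toy_system <- function(n_genes = 3, length_aa = 20, n_trnas = 2,
                            n_ribosomes = 5, copies = 1,
                            trna_per_species = 20, factors = NULL,
                            rates = toy_rate_table(), instant_tc = FALSE,
                            seed = 1) {
  stopifnot(n_genes >= 1, n_trnas >= 1, all(length_aa >= 1))
  codons <- sense_codons()
  if (n_trnas > length(codons))
    stop("codon alphabet too small for the requested number of tRNA species")
  codons <- codons[seq_len(n_trnas)]
  map <- decode_map(data.frame(trna = paste0("t", seq_len(n_trnas)),
                               codon = codons, stringsAsFactors = FALSE))
  usage <- stats::setNames(rep(1 / n_trnas, n_trnas), codons)
  length_aa <- rep_len(length_aa, n_genes)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  genes <- data.frame(
    gene_id = paste0("toy", seq_len(n_genes)),
    length_aa = as.integer(length_aa),
    copies = as.integer(rep_len(copies, n_genes)),
    sequence = vapply(length_aa, function(L)
      paste(sample_gene_codons(L, usage, stop_codon = "UAA"), collapse = " "),
      character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tx <- transcriptome(genes)

  fac <- c(EfTu = 4 * n_ribosomes, EfTs = 2 * n_ribosomes,
           EfG = 2 * n_ribosomes, RF1 = n_ribosomes, RF2 = n_ribosomes,
           RF3 = n_ribosomes, RRF = n_ribosomes)
  if (!is.null(factors)) fac[names(factors)] <- factors
  pools_vec <- c(
    free_30S_PIC = as.integer(n_ribosomes), free_50S = as.integer(n_ribosomes),
    EfTu_GTP = as.integer(fac[["EfTu"]]), EfTu_GDP = 0L, EfTu_Ts = 0L,
    EfTs_free = as.integer(fac[["EfTs"]]),
    EfG_GTP = as.integer(fac[["EfG"]]), EfG_GDP = 0L,
    RF1 = as.integer(fac[["RF1"]]), RF2 = as.integer(fac[["RF2"]]),
    RF3_GTP = as.integer(fac[["RF3"]]), RF3_GDP = 0L,
    RRF = as.integer(fac[["RRF"]]))
  tr <- data.frame(trna = paste0("t", seq_len(n_trnas)),
                   total = as.integer(trna_per_species),
                   deacylated = 0L, charged = 0L, free_tc = 0L,
                   stringsAsFactors = FALSE)
  if (instant_tc) tr$free_tc <- tr$total else tr$charged <- tr$total
  pools <- structure(list(pools = pools_vec, trna = tr),
                     class = "species_pools")
  translation_system(tx, pools, rates, map, instant_tc = instant_tc)
}
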