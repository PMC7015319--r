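#' Toggle explicit ternary-complex formation
#'
#' With the reactions governing EF-Tu binding to newly charged tRNAs turned
#' off, a tRNA ejected from an elongating ribosome returns immediately to
#' the free ternary-complex pool (charging, TC formation and the
#' EF-Tu/EF-Ts cycle are bypassed and the whole tRNA complement starts in
#' free TC). This reproduces the simplifying assumption of coarser
#' translation models and is the comparison arm for quantifying how much of
#' the codon-bias mismatch penalty is carried by competition for EF-Tu:GTP.
#'
#' @param system a [translation_system()].
#' @param off `TRUE` to bypass TC formation (instant recycling), `FALSE`
#'   to restore the explicit reactions.
#' @return A rebuilt `translation_system`.
#' @export
toggle_tc_reactions <- function(system, off = TRUE) {
  translation_system(system$transcriptome, system$pools, system$rates,
                     system$map, system$volume, instant_tc = isTRUE(off))
}

#' Desk-scale cell presets
#'
#' A scaled-down simulated cell (tens of mRNAs, ~100 ribosomes,
#' proportionally scaled factor and tRNA pools) that preserves the
#' ribosome-per-nucleotide density of a full-size fast-growing cell while
#' running in seconds. The preset arms express the standard perturbation
#' experiments as configuration differences on one fixed base cell:
#'
#' * `"matched"` — codon bias of the transcriptome matched to the tRNA
#'   abundances (the baseline).
#' * `"mismatched"` — same genes, lengths and copy numbers, codons
#'   re-sampled from a mismatched usage distribution (a geometric blend
#'   between the matched abundances and a random permutation of them,
#'   giving codon demand up to about three times the tRNA supply share for
#'   the worst species, comparable to the discrepancy between measured
#'   tRNA pools and wild-type codon usage).
#' * `"mismatched_instant_tc"` — the mismatched transcriptome with
#'   ternary-complex formation bypassed (see [toggle_tc_reactions()]).
#' * `"double_eftu"` — matched cell with EF-Tu (and its partner EF-Ts)
#'   doubled.
#' * `"double_all"` — matched cell with tRNAs, EF-Tu, EF-Ts, EF-G, RF1/2/3
#'   and RRF all doubled in unison.
#'
#' All arms share the same kinetic rate table and differ only in
#' transcriptome codon bias, pool multipliers or the TC-formation flag.
#'
#' @param arm which preset arm to build.
#' @param n_mrnas target number of mRNA instances in the base transcriptome
#'   (genes are drawn with sampled copy numbers until this total is crossed).
#' @param n_ribosomes total ribosome count.
#' @param mean_length_aa mean ORF length (log-normal lengths).
#' @param seed integer seed controlling the (shared) base transcriptome and
#'   the mismatch permutation.
#' @param rates kinetic rate table.
#' @param reference_ribosomes ribosome count of the full-size reference cell
#'   (about 1.5e4 at one doubling per hour in 1.0 um^3). The desk cell's
#'   volume is shrunk by `n_ribosomes / reference_ribosomes` so that all
#'   concentrations -- and hence all bimolecular kinetics -- match the
#'   full-size cell.
#' @param min_trna_copies species whose copy number would fall below this
#'   floor at desk scale are excluded (their codons are not used by the
#'   synthetic ORFs and their pools are zero). At 1/150 of cell size the
#'   rarest isoacceptors would otherwise shrink to single molecules, whose
#'   queueing discreteness (and, in polysomes, possible circular waits) is
#'   an artifact of the miniature, not a property of the full-size cell.
#' @param mismatch_blend exponent of the geometric blend
#'   `matched^(1-b) * permuted^b` defining the mismatched abundance vector;
#'   `b = 0.5` caps the worst codon-demand/tRNA-supply ratio near 3.
#' @return A `translation_system`.
#' @export
desk_cell_system <- function(arm = c("matched", "mismatched",
                                     "mismatched_instant_tc",
                                     "double_eftu", "double_all"),
                             n_mrnas = 35, n_ribosomes = 100,
                             mean_length_aa = 75, seed = 2026,
                             rates = default_rate_table(),
                             reference_ribosomes = 15000,
                             min_trna_copies = 6,
                             mismatch_blend = 0.5) {
  arm <- match.arg(arm)
  map <- ecoli_trna_map()
  counts <- trna_counts_theoretical("1.07")
  total_trna <- default_factor_ratios()[["tRNA"]] * n_ribosomes
  scaled <- counts / sum(counts) * total_trna
  counts[scaled < min_trna_copies] <- 0
  # codons decodable only by excluded species must not appear in the ORFs
  keep_map <- map[map$trna %in% names(counts)[counts > 0], , drop = FALSE]
  matched_usage <- suppressWarnings(
    codon_usage_from_trnas(counts[counts > 0], keep_map))
  matched_usage <- matched_usage[matched_usage > 0]
  lengths <- make_synthetic_gene_lengths(4 * n_mrnas,
                                         meanlog = log(mean_length_aa),
                                         sdlog = 0.30, seed = seed + 1)
  tx <- build_transcriptome(lengths, matched_usage, target_n = n_mrnas,
                            replace = TRUE, seed = seed + 2)
  if (arm %in% c("mismatched", "mismatched_instant_tc")) {
    # permuting abundances across species decouples supply from demand while
    # keeping the usage distribution's shape
    old <- globalenv()$.Random.seed
    set.seed(seed + 3)
    nz <- counts > 0
    perm_counts <- counts
    perm_counts[nz] <- sample(unname(counts[nz]))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    mism_counts <- counts
    mism_counts[nz] <- counts[nz]^(1 - mismatch_blend) *
      perm_counts[nz]^mismatch_blend
    mism_usage <- suppressWarnings(
      codon_usage_from_trnas(mism_counts[nz], keep_map))
    mism_usage <- mism_usage[mism_usage > 0]
    tx <- rebuild_with_usage(tx, mism_usage, seed = seed + 4)
  }
  multipliers <- switch(arm,
    double_eftu = c(EfTu = 2, EfTs = 2),
    double_all  = c(tRNA = 2, EfTu = 2, EfTs = 2, EfG = 2,
                    RF1 = 2, RF2 = 2, RF3 = 2, RRF = 2),
    NULL)
  instant <- arm == "mismatched_instant_tc"
  pools <- scale_pools(n_ribosomes,
                       trna_fractions = counts / sum(counts),
                       multipliers = multipliers,
                       initial_trna = if (instant) "free_tc" else "charged")
  translation_system(tx, pools, rates, map,
                     volume = n_ribosomes / reference_ribosomes,
                     instant_tc = instant)
}

#' Read and write simulation configurations
#'
#' A configuration is a plain list (serialised as YAML) holding the run
#' settings (`n_ribosomes`, `t_end`, `seed`, `sample_every`, `volume`,
#' `instant_tc`, optional `multipliers`) plus file references for the rate
#' table, transcriptome FASTA/copies and tRNA abundance table. Every study
#' arm is expressible as a config diff.
#'
#' @param config a configuration list.
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("n_ribosomes", "t_end", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  cfg
}

#' Run manifest
#'
#' A reproducibility record for one run: a hash of the full system
#' definition (transcriptome, pools, rates, decode map, volume, flags), the
#' seed and horizon, and package/R versions. Two runs with identical
#' manifests produce identical trajectories.
#'
#' @param system a [translation_system()].
#' @param t_end,seed the run settings.
#' @return A named list.
#' @export
run_manifest <- function(system, t_end, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  core <- list(genes = system$transcriptome$genes,
               pools = system$pools, rates = as.data.frame(system$rates),
               map = as.data.frame(system$map), volume = system$volume,
               instant_tc = system$instant_tc)
  saveRDS(core, tmp, version = 2)
  list(system_hash = unname(tools::md5sum(tmp)),
       t_end = t_end, seed = seed,
       n_mrna = system$n_mrna, n_nt = system$n_nt,
       n_ribosomes = system$n_ribosomes,
       package_version = as.character(utils::packageVersion("ribosim")),
       r_version = as.character(getRversion()))
}
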