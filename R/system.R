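#' Assemble a translation system
#'
#' Binds together everything one simulated cell needs: the transcriptome
#' (expanded to individual mRNA instances, one per copy), the decode map, the
#' species pools and the kinetic rate table. Validation guarantees that every
#' codon used by the transcriptome is decodable, that the tRNA species of the
#' pools and the decode map agree, and that each mRNA is a well-formed ORF.
#'
#' @param transcriptome a [transcriptome()].
#' @param pools a [scale_pools()] result (or hand-built `species_pools`).
#' @param rates a [rate_table()]; defaults to [default_rate_table()].
#' @param map a [decode_map()].
#' @param volume cell volume in um^3 used to convert second-order rates.
#' @param instant_tc if `TRUE`, ternary-complex formation, tRNA charging and
#'   the EF-Tu/EF-Ts cycle are bypassed: a tRNA ejected from a ribosome
#'   returns directly to the free-TC pool. This reproduces the simplifying
#'   assumption of coarser translation models and is used as a comparison
#'   arm; see [toggle_tc_reactions()].
#' @return A `translation_system` object.
#' @export
translation_system <- function(transcriptome, pools, rates = default_rate_table(),
                               map, volume = 1.0, instant_tc = FALSE) {
  stopifnot(inherits(transcriptome, "transcriptome"),
            inherits(pools, "species_pools"))
  map <- decode_map(map)
  rates <- rate_table(rates)

  if (!setequal(pools$trna$trna, trna_species(map)))
    stop("tRNA species in pools and decode map disagree")
  # order tRNA species as in the pools table
  species <- pools$trna$trna

  genes <- transcriptome$genes
  cl <- codon_list(genes)
  used <- unique(unlist(lapply(cl, function(x) x[2:(length(x) - 1L)])))
  uncovered <- setdiff(used, map$codon)
  if (length(uncovered))
    stop("transcriptome uses codon(s) decoded by no tRNA: ",
         paste(uncovered, collapse = ", "))
  # codons whose every decoding species has zero copies can never be decoded
  zero_sp <- pools$trna$trna[pools$trna$total == 0]
  if (length(zero_sp)) {
    dead <- vapply(used, function(cod) {
      all(map$trna[map$codon == cod] %in% zero_sp)
    }, logical(1))
    if (any(dead))
      warning("codon(s) in the transcriptome are decoded only by species ",
              "with zero tRNA copies (ribosomes reaching them will stall ",
              "forever): ", paste(used[dead], collapse = ", "))
  }

  if (instant_tc) {
    tr <- pools$trna
    tr$free_tc <- tr$total
    tr$charged <- 0L
    tr$deacylated <- 0L
    pools$trna <- tr
  }

  gene_codes <- lapply(cl, codon_code)
  mrna_gene <- rep(seq_len(nrow(genes)), genes$copies)
  trna_codes <- lapply(species, function(t) codon_code(cognate_codons(map, t)))

  sz <- transcriptome_size(transcriptome)
  structure(list(
    transcriptome = transcriptome,
    pools = pools,
    rates = rates,
    map = map,
    volume = volume,
    instant_tc = instant_tc,
    n_mrna = sz$n,
    n_nt = sz$n_nt,
    n_ribosomes = unname(pools$pools[["free_30S_PIC"]]),
    cpp = list(
      gene_codons = gene_codes,
      gene_names = genes$gene_id,
      mrna_gene = as.integer(mrna_gene),
      trna_codons = trna_codes,
      trna_names = species,
      rates_eff = rate_constants(rates, volume),
      instant_tc = instant_tc
    )
  ), class = "translation_system")
}

#' @export
print.translation_system <- function(x, ...) {
  cat("Translation system:", x$n_mrna, "mRNAs (", x$n_nt, "nt ),",
      x$n_ribosomes, "ribosomes,", nrow(x$pools$trna), "tRNA species",
      if (x$instant_tc) "[instant TC recycling]" else "", "\n")
  invisible(x)
}

#' Initial state of a translation system
#'
#' All ribosomal subunits and factors free, tRNAs distributed as configured
#' in the pools, no ribosome bound to any mRNA. States in this layout (free
#' pools + per-mRNA ribosome tables) can also be hand-built to probe the
#' reaction catalogue at arbitrary configurations.
#'
#' @param system a [translation_system()].
#' @return A state list: `pools`, `deacylated`, `charged`, `free_tc`,
#'   `ribosomes` (list of per-mRNA data frames, `NULL` entries = empty).
#' @export
initial_state <- function(system) {
  tr <- system$pools$trna
  list(pools = system$pools$pools,
       deacylated = stats::setNames(tr$deacylated, tr$trna),
       charged = stats::setNames(tr$charged, tr$trna),
       free_tc = stats::setNames(tr$free_tc, tr$trna),
       ribosomes = vector("list", system$n_mrna))
}

.norm_state <- function(system, state) {
  if (is.null(state)) state <- initial_state(system)
  if (is.null(state$ribosomes))
    state$ribosomes <- vector("list", system$n_mrna)
  empty <- data.frame(phase = character(0), p_site = integer(0),
                      a_trna = character(0), p_trna = character(0),
                      rf = integer(0), stringsAsFactors = FALSE)
  state$ribosomes <- lapply(state$ribosomes, function(df) {
    if (is.null(df)) return(empty)
    df$phase <- as.character(df$phase)
    df$p_site <- as.integer(df$p_site)
    if (is.null(df$a_trna)) df$a_trna <- NA_character_
    if (is.null(df$p_trna)) df$p_trna <- NA_character_
    if (is.null(df$rf)) df$rf <- 0L
    df$a_trna <- as.character(df$a_trna)
    df$p_trna <- as.character(df$p_trna)
    df$rf <- as.integer(df$rf)
    df
  })
  state
}

#' Enumerate all currently fireable reactions
#'
#' Lists every reaction available in the given state with its propensity:
#' initiation events on mRNAs with a clear start region, the sub-step
#' reactions of every bound ribosome (ternary-complex binding only for
#' species cognate to the A-site codon, translocation only when the
#' downstream footprint is clear, RF1/RF2 binding according to the identity
#' of the stop codon), and the pool-level reactions (tRNA charging, TC
#' formation, the EF-Tu/EF-Ts and EF-G/RF3 nucleotide-exchange cycles).
#'
#' @param system a [translation_system()].
#' @param state a state list as produced by [initial_state()] (default) or
#'   hand-built; `NULL` means the initial state.
#' @return Data frame `reaction`, `mrna` (0 = pool-level), `p_site`,
#'   `trna`, `propensity` (s^-1).
#' @export
enumerate_reactions <- function(system, state = NULL) {
  state <- .norm_state(system, state)
  cpp_enumerate(system$cpp, state)
}

#' Fire one reaction and return the updated state
#'
#' Applies a single reaction's stoichiometry atomically (advancing the
#' ribosome phase, moving molecules between pools) and returns the new
#' state together with conservation totals. Firing a reaction that is not
#' currently enabled is an error.
#'
#' @inheritParams enumerate_reactions
#' @param reaction reaction name (see [reaction_catalogue()]; RF binding is
#'   addressed as `"rf1_binding"`/`"rf2_binding"`).
#' @param mrna mRNA instance index (0 for pool-level reactions).
#' @param p_site P-site position identifying the ribosome (NA when
#'   unambiguous).
#' @param trna tRNA species for tRNA-specific reactions (`""` when
#'   unambiguous).
#' @export
fire_reaction <- function(system, state = NULL, reaction, mrna = 0L,
                          p_site = NA_integer_, trna = "") {
  state <- .norm_state(system, state)
  cpp_fire(system$cpp, state, reaction, as.integer(mrna),
           as.integer(p_site), trna)
}

#' Conservation totals of a state
#'
#' Scans the full state (free pools plus every bound ribosome and its
#' ligands) and returns the implied total copy number of each conserved
#' species: subunits, EF-Tu (over GTP/GDP/Ts-bound/free-TC/on-ribosome
#' forms), EF-Ts, EF-G, RF1/2/3, RRF, mRNAs and every tRNA species over all
#' charge/complex states.
#'
#' @inheritParams enumerate_reactions
#' @export
species_totals <- function(system, state = NULL) {
  state <- .norm_state(system, state)
  cpp_state_totals(system$cpp, state)
}

#' Steric exclusion of ribosome movement
#'
#' A ribosome occupies an extended footprint of 8 codons 5' of its P site
#' and 6 codons 3' of it, so the minimal centre-to-centre P-site spacing is
#' 8 + 6 + 1 = 15 codons. A forward move is excluded when the current
#' separation from the downstream neighbour is below that minimum, and a
#' 30S subunit cannot load while the 5'-most ribosome's P site is within 15
#' codons of the start codon.
#'
#' @param p,q P-site codon indices (1-based) of the upstream (`p`) and
#'   downstream (`q`) ribosome; vectorised.
#' @return `is_blocked()`: `TRUE` when the upstream ribosome's forward move
#'   is sterically excluded. `initiation_blocked()`: `TRUE` when a new 30S
#'   cannot load given the 5'-most occupied P site `q`.
#' @examples
#' is_blocked(10, 24)  # separation 14: blocked
#' is_blocked(10, 25)  # separation 15: free
#' @export
is_blocked <- function(p, q) (q - p) < 15

#' @rdname is_blocked
#' @export
initiation_blocked <- function(q) (q - 1) < 15
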