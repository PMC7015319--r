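#' tRNA decoding maps
#'
#' A decode map records which codons each tRNA species is cognate to. It is a
#' two-column data frame (`trna`, `codon`), one row per (species, codon) pair;
#' a codon may be decoded by more than one species (cross-recognition), which
#' is what makes the tRNA/codon-usage matching problem under-determined.
#'
#' @param map a data frame with character columns `trna` and `codon`.
#' @param require_full if `TRUE`, every one of the 61 sense codons must be
#'   decoded by at least one species (the invariant for whole-transcriptome
#'   simulations); toy maps covering a codon subset set this to `FALSE`.
#' @return A validated `decode_map` data frame.
#' @examples
#' decode_map(data.frame(trna = c("tA", "tA", "tB"),
#'                       codon = c("AAA", "AAG", "GGC")))
#' @export
decode_map <- function(map, require_full = FALSE) {
  stopifnot(is.data.frame(map), all(c("trna", "codon") %in% names(map)))
  map <- data.frame(trna = as.character(map$trna),
                    codon = toupper(gsub("T", "U", as.character(map$codon))),
                    stringsAsFactors = FALSE)
  codon_code(map$codon) # validates symbols
  if (any(map$codon %in% stop_codons()))
    stop("stop codons are recognised by release factors, not tRNAs")
  if (anyDuplicated(map))
    stop("duplicated (trna, codon) pair in decode map")
  if (require_full) {
    missing <- setdiff(sense_codons(), map$codon)
    if (length(missing))
      stop("sense codons decoded by no tRNA species: ",
           paste(missing, collapse = ", "))
  }
  class(map) <- c("decode_map", "data.frame")
  map
}

#' @rdname decode_map
#' @export
trna_species <- function(map) unique(map$trna)

#' @rdname decode_map
#' @param trna a species name present in `map`.
#' @export
cognate_codons <- function(map, trna) map$codon[map$trna == trna]

#' Representative E. coli tRNA set
#'
#' A curated 42-species tRNA set for *E. coli*-like simulations, using the
#' conventional isoacceptor names (Ala1B, Arg2..Arg5, ..., Val2) and codon
#' assignments that follow standard wobble rules. Every one of the 61 sense
#' codons is decoded by at least one species, and several codons are shared
#' between species (e.g. GCU by Ala1B and Ala2), so the set exercises the
#' cross-recognition degeneracy of the matching problem. The assignments are
#' a representative approximation of the canonical isoacceptor table, not a
#' measured data set.
#'
#' @return A `decode_map` covering all 61 sense codons.
#' @export
ecoli_trna_map <- function() {
  assign_list <- list(
    Ala1B = c("GCA", "GCG", "GCU"),
    Ala2  = c("GCC", "GCU"),
    Arg2  = c("CGU", "CGC", "CGA"),
    Arg3  = c("CGG"),
    Arg4  = c("AGA"),
    Arg5  = c("AGG"),
    Asn   = c("AAU", "AAC"),
    Asp1  = c("GAU", "GAC"),
    Cys   = c("UGU", "UGC"),
    Gln1  = c("CAA"),
    Gln2  = c("CAG"),
    Glu2  = c("GAA", "GAG"),
    Gly1  = c("GGG"),
    Gly2  = c("GGA", "GGG"),
    Gly3  = c("GGU", "GGC"),
    His   = c("CAU", "CAC"),
    Ile1  = c("AUU", "AUC"),
    Ile2  = c("AUA"),
    Leu1  = c("CUG"),
    Leu2  = c("CUU", "CUC"),
    Leu3  = c("CUA", "CUG"),
    Leu4  = c("UUG"),
    Leu5  = c("UUA", "UUG"),
    Lys   = c("AAA", "AAG"),
    Metm  = c("AUG"),
    Phe   = c("UUU", "UUC"),
    Pro1  = c("CCG"),
    Pro2  = c("CCU", "CCC"),
    Pro3  = c("CCA", "CCU"),
    Ser1  = c("UCA", "UCU"),
    Ser2  = c("UCG"),
    Ser3  = c("AGC", "AGU"),
    Ser5  = c("UCC", "UCU"),
    Thr1  = c("ACC", "ACU"),
    Thr2  = c("ACG"),
    Thr3  = c("ACC", "ACU"),
    Thr4  = c("ACA"),
    Trp   = c("UGG"),
    Tyr1  = c("UAU", "UAC"),
    Tyr2  = c("UAU", "UAC"),
    Val1  = c("GUA", "GUG", "GUU"),
    Val2  = c("GUC", "GUU")
  )
  decode_map(data.frame(
    trna = rep(names(assign_list), lengths(assign_list)),
    codon = unlist(assign_list, use.names = FALSE),
    stringsAsFactors = FALSE
  ), require_full = TRUE)
}

#' Theoretical tRNA abundances matched to ORF codon usage
#'
#' tRNA copy numbers per cell for an *E. coli* K-12-like cell at three growth
#' rates, derived under the assumption that the share of each isoacceptor in
#' the total tRNA pool matches the usage frequency of the codons it decodes.
#' This is one feasible solution of the tRNA/codon-usage matching problem
#' (cross-recognition makes the solution non-unique). Shipped as a plain-text
#' table under `inst/extdata/`.
#'
#' @param mu growth rate label, one of `"0.70"`, `"1.07"`, `"2.50"`
#'   (doublings per hour).
#' @return A named integer vector of tRNA copy numbers (names as in
#'   [ecoli_trna_map()]).
#' @export
trna_counts_theoretical <- function(mu = c("1.07", "0.70", "2.50")) {
  mu <- match.arg(as.character(mu), c("1.07", "0.70", "2.50"))
  path <- system.file("extdata", "trna_theoretical_counts.tsv",
                      package = "ribosim", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  col <- c("0.70" = "mu_0.70", "1.07" = "mu_1.07", "2.50" = "mu_2.50")[[mu]]
  stats::setNames(as.integer(tab[[col]]), tab$trna)
}
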