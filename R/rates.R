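#' Kinetic rate tables
#'
#' The reaction catalogue is driven by a rate table: one named rate per
#' reaction sub-step, with its kinetic order. First-order rates are in
#' s^-1; second-order rates are in M^-1 s^-1 and are converted to per-pair
#' propensity factors k/(N_A * v) for a cell of volume `v` (default 1.0 um^3).
#' Constant amino-acid and NTP concentrations are folded into the effective
#' first-order rates of the lumped reactions (aminoacylation, nucleotide
#' exchange).
#'
#' `default_rate_table()` ships plausible literature-scale values chosen so
#' that a factor-replete cell elongates at 15-20 aa/s; any or all of them can
#' be replaced from a TSV with [read_rate_table()].
#'
#' @name rate_table
NULL

.REACTIONS <- data.frame(
  reaction = c("pic_binding", "subunit_joining", "tc_binding",
               "gtpase_hydrolysis", "accommodation", "tc_rejection",
               "peptidyl_transfer", "efg_binding", "translocation",
               "rf_binding", "peptide_release", "rf_dissociation",
               "rrf_binding", "recycling", "aminoacylation", "tc_formation",
               "efts_binding", "efts_exchange", "efg_exchange",
               "rf3_exchange"),
  order = c(2L, 2L, 2L,
            1L, 1L, 1L,
            1L, 2L, 1L,
            2L, 1L, 2L,
            2L, 1L, 1L, 2L,
            2L, 1L, 1L,
            1L),
  stringsAsFactors = FALSE
)

#' @describeIn rate_table the catalogue of reaction names with kinetic orders.
#' @export
reaction_catalogue <- function() .REACTIONS

#' @describeIn rate_table the shipped default rate table.
#' @export
default_rate_table <- function() {
  rates <- c(
    pic_binding       = 1.0e7,  # 30S:PIC x mRNA start region
    subunit_joining   = 1.0e8,  # 50S x 30S IC
    tc_binding        = 1.2e8,  # ternary complex x ribosomal A site
    gtpase_hydrolysis = 250,    # activation + GTP hydrolysis on EF-Tu, lumped
    accommodation     = 150,    # aa-tRNA accommodation, EF-Tu:GDP leaves
    tc_rejection      = 0,      # proofreading rejection branch (off by default)
    peptidyl_transfer = 200,
    efg_binding       = 1.5e8,  # EF-G:GTP x pre-translocation ribosome
    translocation     = 80,
    rf_binding        = 5.0e7,  # RF1/RF2 x stop codon in A site
    peptide_release   = 15,
    rf_dissociation   = 5.0e7,  # RF3:GTP-stimulated RF release
    rrf_binding       = 5.0e7,
    recycling         = 15,     # subunit splitting; 30S re-enters as PIC
    aminoacylation    = 5,      # lumped synthetase charging, per deacylated tRNA
    tc_formation      = 1.2e8,  # charged tRNA x EF-Tu:GTP
    efts_binding      = 3.0e7,  # EF-Ts x EF-Tu:GDP
    efts_exchange     = 30,     # GDP/GTP exchange + EF-Ts release, lumped
    efg_exchange      = 150,    # EF-G GDP -> GTP
    rf3_exchange      = 100     # RF3  GDP -> GTP
  )
  tab <- .REACTIONS
  tab$rate <- unname(rates[tab$reaction])
  tab$units <- ifelse(tab$order == 2L, "M^-1 s^-1", "s^-1")
  rate_table(tab)
}

#' @describeIn rate_table validate a data frame as a rate table. Every
#'   catalogued reaction must be present, with the catalogued kinetic order
#'   and a nonnegative rate.
#' @param tab a data frame with columns `reaction`, `order`, `rate`
#'   (and optionally `units`).
#' @export
rate_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("reaction", "order", "rate") %in% names(tab)))
  missing <- setdiff(.REACTIONS$reaction, tab$reaction)
  if (length(missing))
    stop("missing rate entry for reaction(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(tab$reaction, .REACTIONS$reaction)
  if (length(extra))
    stop("unknown reaction(s) in rate table: ", paste(extra, collapse = ", "))
  tab <- tab[match(.REACTIONS$reaction, tab$reaction), , drop = FALSE]
  if (!all(tab$order == .REACTIONS$order))
    stop("kinetic order disagrees with the catalogue for: ",
         paste(tab$reaction[tab$order != .REACTIONS$order], collapse = ", "))
  if (any(!is.finite(tab$rate) | tab$rate < 0))
    stop("rates must be finite and nonnegative")
  if (is.null(tab$units))
    tab$units <- ifelse(tab$order == 2L, "M^-1 s^-1", "s^-1")
  rownames(tab) <- NULL
  class(tab) <- c("rate_table", "data.frame")
  tab
}

#' @describeIn rate_table read a rate table from TSV
#'   (columns `reaction`, `order`, `rate`, optionally `units`).
#' @param path file path.
#' @export
read_rate_table <- function(path) {
  rate_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @describeIn rate_table write a rate table to TSV.
#' @export
write_rate_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Effective per-molecule rate constants
#'
#' Converts a rate table into the effective constants used in propensities:
#' first-order rates pass through; second-order rates k (M^-1 s^-1) become
#' k/(N_A * v) per pair of reactant molecules, for cell volume `volume`
#' (um^3).
#'
#' @param tab a [rate_table()].
#' @param volume cell volume in um^3 (default 1.0; within the physiological
#'   range the choice has negligible effect on the kinetics).
#' @return A named numeric vector of effective rate constants (s^-1 per
#'   reactant molecule pair or per molecule).
#' @export
rate_constants <- function(tab = default_rate_table(), volume = 1.0) {
  tab <- rate_table(tab)
  stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0)
  avogadro <- 6.02214076e23
  conv <- avogadro * volume * 1e-15 # molecules per molar in v litres
  eff <- ifelse(tab$order == 2L, tab$rate / conv, tab$rate)
  stats::setNames(eff, tab$reaction)
}
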