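#' Molecular species pools
#'
#' A `species_pools` object holds the integer copy numbers of every free
#' molecular species in the cell: ribosomal subunits (the 30S side is
#' pre-lumped with its initiation factors and initiator tRNA into a
#' 30S pre-initiation complex pool), the EF-Tu/EF-Ts and EF-G cycles, release
#' and recycling factors, and each tRNA species in its three free states
#' (deacylated, charged, in free ternary complex).
#'
#' Factor abundances are assumed to scale linearly with the number of
#' ribosomes, so a cell is specified by its ribosome count plus a table of
#' per-ribosome ratios; [scale_pools()] performs the scaling (and applies any
#' perturbation multipliers, e.g. a doubled EF-Tu arm).
#'
#' @name species_pools
NULL

.FACTOR_RATIO_NAMES <- c("30S", "50S", "EfTu", "EfTs", "EfG",
                         "RF1", "RF2", "RF3", "RRF", "tRNA")

#' @describeIn species_pools default per-ribosome abundance ratios. The
#'   ratios follow the physiological rank order in exponentially growing
#'   *E. coli*: EF-Tu is by far the most abundant factor (several copies per
#'   ribosome), EF-Ts/EF-G are of order one per ribosome, release and
#'   recycling factors are sub-stoichiometric, and total tRNA runs at several
#'   copies per ribosome.
#' @export
default_factor_ratios <- function() {
  c(`30S` = 1.0, `50S` = 1.0, EfTu = 8.0, EfTs = 1.0, EfG = 1.5,
    RF1 = 0.15, RF2 = 0.25, RF3 = 0.25, RRF = 0.5, tRNA = 9.0)
}

#' Scale molecular pools with ribosome count
#'
#' @param n_ribosomes total number of ribosomes (= total 30S = total 50S).
#' @param ratios named per-ribosome ratios; see [default_factor_ratios()].
#' @param trna_fractions named vector giving each tRNA species' share of the
#'   total tRNA pool (will be normalised to sum to 1). Names define the tRNA
#'   species of the cell.
#' @param multipliers optional named multipliers applied to a subset of
#'   `ratios` names (e.g. `c(EfTu = 2, EfTs = 2)` for a doubled-EF-Tu/Ts
#'   arm, or `c(tRNA = 2)` to double all tRNAs).
#' @param initial_trna one of `"charged"`, `"free_tc"`, `"deacylated"`:
#'   which state the tRNA pool starts in (the charging/TC-formation reactions
#'   redistribute it during burn-in). Instant-recycling runs use `"free_tc"`.
#' @return A `species_pools` object: `$pools` (named integer vector of the
#'   13 factor pools, all factors starting in their active GTP forms) and
#'   `$trna` (data frame `trna`, `total`, `deacylated`, `charged`,
#'   `free_tc`).
#' @examples
#' pools <- scale_pools(100, trna_fractions = c(tA = 0.5, tB = 0.5))
#' pools$pools[["EfTu_GTP"]]
#' @export
scale_pools <- function(n_ribosomes,
                        ratios = default_factor_ratios(),
                        trna_fractions,
                        multipliers = NULL,
                        initial_trna = c("charged", "free_tc", "deacylated")) {
  initial_trna <- match.arg(initial_trna)
  stopifnot(is.numeric(n_ribosomes), length(n_ribosomes) == 1L,
            n_ribosomes >= 1)
  missing <- setdiff(.FACTOR_RATIO_NAMES, names(ratios))
  if (length(missing))
    stop("missing per-ribosome ratio for species: ",
         paste(missing, collapse = ", "))
  if (any(ratios < 0)) stop("ratios must be nonnegative")
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), .FACTOR_RATIO_NAMES)
    if (length(bad))
      stop("multipliers name unknown species group(s): ",
           paste(bad, collapse = ", "))
    ratios[names(multipliers)] <- ratios[names(multipliers)] * multipliers
  }
  stopifnot(is.numeric(trna_fractions), length(trna_fractions) >= 1,
            !is.null(names(trna_fractions)), all(trna_fractions >= 0),
            sum(trna_fractions) > 0)
  fr <- trna_fractions / sum(trna_fractions)

  cnt <- function(nm) as.integer(round(ratios[[nm]] * n_ribosomes))
  pools <- c(
    free_30S_PIC = cnt("30S"),
    free_50S     = cnt("50S"),
    EfTu_GTP     = cnt("EfTu"),
    EfTu_GDP     = 0L,
    EfTu_Ts      = 0L,
    EfTs_free    = cnt("EfTs"),
    EfG_GTP      = cnt("EfG"),
    EfG_GDP      = 0L,
    RF1          = cnt("RF1"),
    RF2          = cnt("RF2"),
    RF3_GTP      = cnt("RF3"),
    RF3_GDP      = 0L,
    RRF          = cnt("RRF")
  )
  total_trna <- round(ratios[["tRNA"]] * n_ribosomes)
  totals <- as.integer(round(fr * total_trna))
  trna <- data.frame(trna = names(fr), total = totals,
                     deacylated = 0L, charged = 0L, free_tc = 0L,
                     stringsAsFactors = FALSE)
  trna[[c(charged = "charged", free_tc = "free_tc",
          deacylated = "deacylated")[[initial_trna]]]] <- totals
  structure(list(pools = pools, trna = trna), class = "species_pools")
}

#' @export
print.species_pools <- function(x, ...) {
  cat("Species pools:", sum(x$pools[c("free_30S_PIC")]), "ribosomes (30S),",
      sum(x$trna$total), "tRNAs over", nrow(x$trna), "species\n")
  print(x$pools)
  invisible(x)
}

#' Read/write species tables
#'
#' TSV interface for species counts: columns `species`, `count`. tRNA rows
#' use names `tRNA:<species>:<state>` with state one of `deacylated`,
#' `charged`, `free_tc`.
#'
#' @param pools a `species_pools` object.
#' @param path file path.
#' @export
write_species_table <- function(pools, path) {
  tr <- pools$trna
  rows <- rbind(
    data.frame(species = names(pools$pools), count = unname(pools$pools),
               stringsAsFactors = FALSE),
    data.frame(species = c(paste0("tRNA:", tr$trna, ":deacylated"),
                           paste0("tRNA:", tr$trna, ":charged"),
                           paste0("tRNA:", tr$trna, ":free_tc")),
               count = c(tr$deacylated, tr$charged, tr$free_tc),
               stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_table
#' @export
read_species_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "count") %in% names(tab)))
  is_trna <- startsWith(tab$species, "tRNA:")
  fix <- tab[!is_trna, , drop = FALSE]
  pools <- stats::setNames(as.integer(fix$count), fix$species)
  parts <- strsplit(tab$species[is_trna], ":", fixed = TRUE)
  tr <- data.frame(trna = vapply(parts, `[[`, "", 2L),
                   state = vapply(parts, `[[`, "", 3L),
                   count = as.integer(tab$count[is_trna]),
                   stringsAsFactors = FALSE)
  species <- unique(tr$trna)
  get <- function(state) {
    m <- tr[tr$state == state, ]
    stats::setNames(m$count, m$trna)[species]
  }
  trna <- data.frame(trna = species,
                     deacylated = unname(get("deacylated")),
                     charged = unname(get("charged")),
                     free_tc = unname(get("free_tc")),
                     stringsAsFactors = FALSE)
  trna[is.na(trna)] <- 0L
  trna$total <- trna$deacylated + trna$charged + trna$free_tc
  trna <- trna[, c("trna", "total", "deacylated", "charged", "free_tc")]
  structure(list(pools = pools, trna = trna), class = "species_pools")
}
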