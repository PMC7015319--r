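#' Peptide chain elongation rates
#'
#' Each completed protein yields one rate: amino acids incorporated during
#' elongation divided by the duration of its elongation phase (from 70S
#' formation at the start codon to the translocation that exposes the stop
#' codon; initiation and termination dwell times are excluded, switchable).
#' `elongation_rates()` returns the per-protein rates with a trailing
#' running mean; `peptide_elongation_rate()` returns the steady-state
#' average over the quasi-steady tail of the run.
#'
#' @param sim a `translation_sim` (or a data frame shaped like its
#'   `completions` component).
#' @param window running-mean window, in protein-completion events.
#' @param denominator `"elongation"` (default) or `"total"` (include
#'   initiation and termination dwell).
#' @return `elongation_rates()`: data frame `t` (completion time), `gene`,
#'   `rate`, `running` (NA until `window` completions have accrued).
#' @export
elongation_rates <- function(sim, window = 1000,
                             denominator = c("elongation", "total")) {
  denominator <- match.arg(denominator)
  cmp <- if (is.data.frame(sim)) sim else sim$completions
  if (!nrow(cmp)) stop("no completed proteins in this run")
  dur <- switch(denominator,
                elongation = cmp$t_elong_end - cmp$t_elong_begin,
                total = cmp$t_release - cmp$t_init)
  if (any(dur <= 0)) stop("zero-duration completion record")
  ord <- order(cmp$t_elong_end)
  rate <- (cmp$length_aa / dur)[ord]
  run <- rep(NA_real_, length(rate))
  if (length(rate) >= window) {
    cs <- cumsum(rate)
    idx <- window:length(rate)
    run[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  }
  data.frame(t = cmp$t_elong_end[ord], gene = cmp$gene[ord], rate = rate,
             running = run, stringsAsFactors = FALSE)
}

#' @rdname elongation_rates
#' @param tail_fraction fraction of simulated time treated as the
#'   quasi-steady tail (completions before it are burn-in and discarded).
#' @export
peptide_elongation_rate <- function(sim, tail_fraction = 0.5,
                                    denominator = c("elongation", "total")) {
  denominator <- match.arg(denominator)
  cmp <- if (is.data.frame(sim)) sim else sim$completions
  t_final <- if (is.data.frame(sim)) max(cmp$t_elong_end) else sim$t_final
  keep <- cmp$t_elong_end >= (1 - tail_fraction) * t_final
  if (!any(keep)) keep <- rep(TRUE, nrow(cmp))
  cmp <- cmp[keep, , drop = FALSE]
  dur <- switch(denominator,
                elongation = cmp$t_elong_end - cmp$t_elong_begin,
                total = cmp$t_release - cmp$t_init)
  if (!length(dur)) return(NA_real_)
  if (any(dur <= 0)) stop("zero-duration completion record")
  mean(cmp$length_aa / dur)
}

#' Ribosome state fractions
#'
#' Classifies every ribosome (50S-equivalent) at each checkpoint as free,
#' initiating (still positioned at the start codon, with or without a joined
#' 50S), elongating, or terminating, and averages over the quasi-steady
#' tail. Percentages are relative to the total ribosome count. The stalled
#' percentage counts elongating ribosomes whose only forward reaction is
#' sterically blocked translocation or whose A-site codon has no cognate
#' free ternary complex; it is reported both relative to elongating
#' ribosomes (`pct_stalled_of_elongating`, the convention used in summary
#' tables) and relative to all ribosomes (`pct_stalled`).
#'
#' @param sim a `translation_sim`.
#' @param tail_fraction fraction of simulated time used for the average.
#' @return One-row data frame: `pct_initiating`, `pct_elongating`,
#'   `pct_terminating`, `pct_stalled`, `pct_stalled_of_elongating`,
#'   `pct_free_50S`, `pct_free_30S_PIC`, `beta_r` (= 100 - pct_free_50S).
#' @export
state_fractions <- function(sim, tail_fraction = 0.5) {
  ck <- sim$checkpoints
  keep <- ck$time >= (1 - tail_fraction) * sim$t_final
  if (sum(keep) < 1) keep <- rep(TRUE, nrow(ck))
  ck <- ck[keep, , drop = FALSE]
  tot <- sim$n_ribosomes
  pc <- function(v) 100 * mean(v) / tot
  el <- mean(ck$elongating)
  data.frame(
    pct_initiating = pc(ck$initiating),
    pct_elongating = pc(ck$elongating),
    pct_terminating = pc(ck$terminating),
    pct_stalled = pc(ck$stalled),
    pct_stalled_of_elongating = if (el > 0) 100 * mean(ck$stalled) / el else 0,
    pct_free_50S = pc(ck$free_50S),
    pct_free_30S_PIC = pc(ck$free_30S_PIC),
    beta_r = 100 - pc(ck$free_50S)
  )
}

#' Free ternary-complex fraction per tRNA species
#'
#' Time-averaged ratio of each tRNA species' free-TC count to its total
#' copy number, over the trailing `window` seconds of the run. In a
#' transcriptome whose codon bias matches the tRNA abundances this ratio is
#' roughly uniform across species; under mismatch, over-demanded species
#' are drained (they lose the competition for EF-Tu:GTP) and under-demanded
#' ones accumulate in free TC.
#'
#' @param sim a `translation_sim`.
#' @param window trailing averaging window in simulated seconds.
#' @param sort_output order rows by ascending fraction (the conventional
#'   presentation).
#' @return Data frame `trna`, `fraction`, `total`.
#' @export
free_tc_fractions <- function(sim, window = 100, sort_output = TRUE) {
  ck_t <- sim$checkpoints$time
  if (sim$t_final <= 0) stop("empty trajectory")
  keep <- ck_t >= sim$t_final - window
  m <- sim$free_tc[keep, , drop = FALSE]
  tot <- sim$trna_totals[colnames(m)]
  frac <- colMeans(m) / pmax(tot, 1)
  out <- data.frame(trna = colnames(m), fraction = unname(frac),
                    total = unname(tot), stringsAsFactors = FALSE)
  if (sort_output) out <- out[order(out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-codon decoding statistics
#'
#' Mean A-site decoding time (from A-site vacancy to peptidyl transfer),
#' event count and stalling frequency for each sense codon. Works on a
#' `translation_sim` (using the engine's per-codon aggregation) or on a raw
#' decode-event log data frame with columns `codon`, `wait`, `stalled`.
#'
#' @param x a `translation_sim` or a decode-log data frame.
#' @return Data frame `codon`, `n_events`, `mean_wait`, `stall_frequency`,
#'   restricted to codons with at least one event.
#' @export
codon_decode_stats <- function(x) {
  if (inherits(x, "translation_sim")) {
    cs <- x$codon_stats
    cs <- cs[cs$n_events > 0, , drop = FALSE]
    out <- data.frame(codon = cs$codon, n_events = cs$n_events,
                      mean_wait = cs$total_wait / cs$n_events,
                      stall_frequency = cs$n_stalled / cs$n_events,
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(x), all(c("codon", "wait", "stalled") %in% names(x)))
    if (!nrow(x)) stop("empty decode log")
    sp <- split(x, x$codon)
    out <- data.frame(
      codon = names(sp),
      n_events = vapply(sp, nrow, numeric(1)),
      mean_wait = vapply(sp, function(d) mean(d$wait), numeric(1)),
      stall_frequency = vapply(sp, function(d) mean(as.numeric(d$stalled)),
                               numeric(1)),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Mean ribosome spacing and density
#'
#' The average nucleotide centre-to-centre distance between ribosomes over
#' the whole transcriptome is d_r = N_nt / (beta_r * N_50), where N_nt is
#' the transcriptome's total nucleotide count, beta_r the ribosome activity
#' (fraction of subunits engaged in translation) and N_50 the total number
#' of 50S subunits; the density is rho = 1/d_r ribosomes per nucleotide.
#' d_r has a physical floor at the extended ribosome footprint (15 codons =
#' 45 nt); values below it are impossible and trigger a warning.
#'
#' @param n_nt total nucleotides in the transcriptome.
#' @param beta_r ribosome activity as a fraction in (0, 1].
#' @param n_50 total 50S subunits.
#' @return List with `d_r` (nt) and `rho` (ribosomes/nt).
#' @examples
#' ribosome_spacing(1000, 0.5, 20)  # d_r = 100, rho = 0.01
#' @export
ribosome_spacing <- function(n_nt, beta_r, n_50) {
  stopifnot(n_nt > 0, beta_r > 0, n_50 > 0)
  if (beta_r > 1) stop("beta_r is a fraction in (0, 1]")
  d_r <- n_nt / (beta_r * n_50)
  if (d_r < 45)
    warning("d_r = ", round(d_r, 2),
            " nt is below the 45-nt ribosome footprint: physically impossible")
  list(d_r = d_r, rho = 1 / d_r)
}

#' One-row summary panel of a run
#'
#' The standard efficiency summary: transcriptome size, steady-tail peptide
#' chain elongation rate C_p, ribosome state percentages, ribosome activity
#' beta_r and mean ribosome spacing d_r / density rho.
#'
#' @param sim a `translation_sim`.
#' @param tail_fraction quasi-steady tail used for averaging.
#' @export
summary_panel <- function(sim, tail_fraction = 0.5) {
  fr <- state_fractions(sim, tail_fraction)
  cp <- if (nrow(sim$completions)) peptide_elongation_rate(sim, tail_fraction)
        else NA_real_
  sp <- ribosome_spacing(sim$n_nt, fr$beta_r / 100, sim$n_ribosomes)
  data.frame(n_mrna = sim$n_mrna, n_nt = sim$n_nt,
             n_ribosomes = sim$n_ribosomes, c_p = cp,
             pct_initiating = fr$pct_initiating,
             pct_elongating = fr$pct_elongating,
             pct_terminating = fr$pct_terminating,
             pct_stalled = fr$pct_stalled,
             pct_stalled_of_elongating = fr$pct_stalled_of_elongating,
             pct_free_50S = fr$pct_free_50S,
             beta_r = fr$beta_r, d_r = sp$d_r, rho = sp$rho)
}

#' Mean and dispersion over replicate runs
#'
#' Collates [summary_panel()] rows of replicate simulations (same system,
#' different seeds) into mean and standard deviation per quantity.
#'
#' @param sims list of `translation_sim` objects.
#' @param tail_fraction passed to [summary_panel()].
#' @return Data frame with one row per quantity: `mean`, `sd`, `n`.
#' @export
summarize_runs <- function(sims, tail_fraction = 0.5) {
  panels <- do.call(rbind, lapply(sims, summary_panel, tail_fraction))
  num <- panels[vapply(panels, is.numeric, logical(1))]
  data.frame(quantity = names(num),
             mean = vapply(num, mean, numeric(1)),
             sd = vapply(num, stats::sd, numeric(1)),
             n = nrow(panels), row.names = NULL, stringsAsFactors = FALSE)
}
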