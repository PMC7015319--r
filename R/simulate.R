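#' Simulate translation of a whole transcriptome
#'
#' Runs the exact stochastic simulation: reactions fire one at a time with
#' exponential waiting times 1/Phi, where Phi is the total propensity; the
#' mRNA (or the pool-reaction group) is selected by descending a binary tree
#' whose leaves hold the per-mRNA propensity sums phi_i, and the reaction
#' within the selected mRNA by a linear scan of its (small) local reaction
#' list. After each firing only the affected leaves are updated, so one
#' event costs O(log2 N) in the number of mRNAs. Pool-coupled propensities
#' (all of the form k_eff x pool x n_waiting) are delta-updated exactly on
#' the mRNAs holding waiters for the changed pool.
#'
#' A naive direct-method engine (`engine = "naive"`) enumerates every
#' reaction afresh at every step and selects by a single linear scan; it
#' shares the kinetics but none of the selection machinery, and exists as
#' the statistical reference for the tree engine.
#'
#' @param system a [translation_system()].
#' @param t_end simulated end time (seconds).
#' @param seed integer seed; the trajectory is fully reproducible from it
#'   (the engine carries its own RNG and does not touch R's).
#' @param sample_every observer cadence in simulated seconds (0 disables
#'   intermediate checkpoints; initial and final states are always
#'   recorded).
#' @param engine `"tree"` (default) or `"naive"`.
#' @param state optional starting state (default [initial_state()]).
#' @param max_events stop after this many reaction events.
#' @param check_every spot-check cadence (events) at which the maintained
#'   total propensity is compared against a full recomputation (tree engine
#'   only; 0 disables). A relative deviation above 1e-6 aborts the run.
#' @param resync_every cadence (events) of a full propensity rebuild to
#'   keep floating-point drift at bay.
#' @param keep_decode_log keep the raw per-event decode log (time, codon,
#'   tRNA, A-site waiting time, stalled flag) up to `decode_log_max` rows.
#' @param decode_log_max cap on raw decode-log rows.
#' @param track_min_separation record the minimal P-site separation ever
#'   observed between neighbouring ribosomes (costs a scan of the fired
#'   mRNA per event).
#' @return A `translation_sim` object. Principal components:
#'   `completions` (one row per finished protein: gene, length, initiation
#'   and elongation-phase times), `checkpoints` (ribosome state census over
#'   time), `free_tc` (checkpoint matrix of per-species free-TC counts),
#'   `codon_stats` (per-codon decode event counts, total waiting time,
#'   stall counts), `final_state`, `status` (`"completed"`, `"deadlock"` or
#'   `"max_events"`), `starved` (channels with waiters but empty pools, on
#'   deadlock).
#' @export
simulate_translation <- function(system, t_end, seed,
                                 sample_every = 1,
                                 engine = c("tree", "naive"),
                                 state = NULL,
                                 max_events = Inf,
                                 check_every = 1000,
                                 resync_every = 10000,
                                 keep_decode_log = FALSE,
                                 decode_log_max = 2e6,
                                 track_min_separation = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(system, "translation_system"),
            is.numeric(t_end), t_end >= 0, is.numeric(seed))
  state <- .norm_state(system, state)
  opts <- list(t_end = as.numeric(t_end), seed = as.numeric(seed),
               sample_every = as.numeric(sample_every), engine = engine,
               max_events = if (is.finite(max_events)) as.numeric(max_events)
                            else 9e15,
               check_every = as.numeric(check_every),
               resync_every = as.numeric(resync_every),
               keep_decode_log = isTRUE(keep_decode_log),
               decode_log_max = as.numeric(decode_log_max),
               track_min_separation = isTRUE(track_min_separation))
  res <- cpp_simulate(system$cpp, state, opts)
  res$n_mrna <- system$n_mrna
  res$n_nt <- system$n_nt
  res$n_ribosomes <- system$n_ribosomes
  res$t_end <- t_end
  res$seed <- seed
  res$engine <- engine
  res$instant_tc <- system$instant_tc
  res$trna_totals <- stats::setNames(system$pools$trna$total,
                                     system$pools$trna$trna)
  class(res) <- "translation_sim"
  res
}

#' @export
print.translation_sim <- function(x, ...) {
  cat("Translation simulation:", format(x$n_events, big.mark = ","),
      "events to t =", round(x$t_final, 3), "s [", x$status, "]\n")
  cat("  mRNAs:", x$n_mrna, " ribosomes:", x$n_ribosomes,
      " proteins completed:", nrow(x$completions), "\n")
  if (nrow(x$completions) > 0) {
    cp <- peptide_elongation_rate(x)
    cat("  mean peptide chain elongation rate (steady tail):",
        round(cp, 2), "aa/s\n")
  }
  if (x$status == "deadlock" && length(x$starved))
    cat("  starved channels:", paste(x$starved, collapse = ", "), "\n")
  invisible(x)
}

#' Minimal trajectory plot
#'
#' Base-graphics time courses of the ribosome state census (initiating,
#' elongating, terminating, stalled, free 50S and free 30S:PIC, as
#' percentages of total ribosomes).
#'
#' @param x a `translation_sim`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.translation_sim <- function(x, ...) {
  ck <- x$checkpoints
  tot <- x$n_ribosomes
  y <- 100 * cbind(I = ck$initiating, E = ck$elongating, T = ck$terminating,
                   S = ck$stalled, `50S` = ck$free_50S,
                   `30S:PIC` = ck$free_30S_PIC) / tot
  graphics::matplot(ck$time, y, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "% of ribosomes", ...)
  graphics::legend("topright", colnames(y), col = seq_len(ncol(y)), lty = 1,
                   cex = 0.8)
  invisible(x)
}

#' Sample exponential waiting times from the engine's RNG
#'
#' Draws inter-event times dt ~ Exponential(Phi) exactly as the simulation
#' loop does, exposed for calibration checks.
#'
#' @param n number of draws.
#' @param phi total propensity (s^-1).
#' @param seed integer seed.
#' @export
draw_waiting_times <- function(n, phi, seed) cpp_draw_dt(n, phi, seed)
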