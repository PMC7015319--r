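---
title: "Whole-cell stochastic simulation of prokaryotic translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-cell stochastic simulation of prokaryotic translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosim)
```

## The model

`ribosim` simulates protein synthesis in a prokaryotic cell as one large
system of elementary chemical reactions, advanced by the exact Gillespie
stochastic simulation algorithm. The simulated cell holds:

* a transcriptome of `N` mRNA instances, each an explicit codon sequence
  (start codon, sense codons, stop codon), each possibly occupied by many
  ribosomes (polysomes);
* finite pools of 30S and 50S ribosomal subunits. The 30S side is pre-lumped
  with its initiation factors and initiator tRNA into a single
  30S pre-initiation complex (30S:PIC) pool — the model's initiation
  currency;
* elongation factor pools: EF-Tu in its GTP, GDP and Ts-bound forms, free
  EF-Ts, EF-G in GTP/GDP forms;
* termination/recycling factors RF1, RF2, RF3 (GTP/GDP) and RRF;
* every tRNA species in three free states — deacylated, charged
  (aminoacylated), and in free ternary complex (TC,
  aa-tRNA·EF-Tu·GTP) — plus whatever copies are bound to ribosomes.

A ribosome walks an ordered sub-step cycle. Initiation: a 30S:PIC binds an
unoccluded start region, then a free 50S joins. Elongation, per codon: a
cognate TC binds the empty A site; GTPase activation/hydrolysis on EF-Tu;
accommodation of the aa-tRNA (EF-Tu:GDP leaves; an optional proofreading
rejection branch exists with default rate zero); peptidyl transfer;
EF-G:GTP binding; translocation, which advances the P site by one codon,
releases the E-site (previous P-site) tRNA as deacylated and EF-G as
EF-G:GDP. Termination, when a stop codon enters the A site: class-specific
release-factor binding (UAG by RF1, UGA by RF2, UAA by either),
peptide release, RF3:GTP-stimulated RF dissociation, RRF binding, and
recycling, which frees the 50S, returns the 30S to the PIC pool and
releases the last deacylated tRNA.

Pool-level ("global") reactions close the loops: per-species lumped
aminoacylation (deacylated to charged; the many synthetase sub-steps are
not resolved, and constant amino-acid/ATP levels are folded into one
effective first-order rate), TC formation (charged tRNA + EF-Tu:GTP),
EF-Tu:GDP + EF-Ts association and lumped nucleotide exchange, and EF-G and
RF3 GDP-to-GTP exchange. Totals of every factor, subunit, tRNA species and
mRNA are conserved exactly: the model describes a quasi-steady cell in
exponential growth, with no synthesis or degradation of machinery within a
run.

Because tRNAs compete for a finite EF-Tu:GTP pool, codon usage that is
mismatched to tRNA abundances redistributes the free-TC pool: over-demanded
species are drained (they lose the competition for EF-Tu) while
under-demanded ones accumulate, slowing decoding at the very codons that
are most used. This coupling — absent from models that return ejected tRNAs
straight to the TC pool — is the scientific focus of the package, and the
`instant_tc` switch (see `toggle_tc_reactions()`) exists precisely to
quantify it.

## Steric exclusion

A ribosome occupies an extended footprint of 8 codons 5' of its P site and
6 codons 3' of it; the minimal centre-to-centre P-site spacing is therefore
8 + 6 + 1 = 15 codons. The operational rule is: a forward move
(translocation) is allowed when the current separation to the downstream
neighbour is at least 15 codons, and 30S loading is allowed when the
5'-most P site is at least 16 codons from the start. The boundary is
half-open by design: a move at separation exactly 15 is permitted, so the
smallest instantaneously observable separation is 14 codons (footprints
touching). `is_blocked(10, 24)` is `TRUE`, `is_blocked(10, 25)` is `FALSE`,
and the engine asserts the ≥ 14 floor when asked to track separations.

## Event selection in logarithmic time

The total propensity is split per mRNA:
`Phi = sum_i phi_i + phi_G`, where `phi_i` sums every reaction local to
mRNA `i` (initiation on it, each of its ribosomes' next sub-steps) and
`phi_G` the pool-level group. The `phi_i` sit on the leaves of a binary
tree whose internal nodes hold partial sums and whose root is `Phi`.
Each event: draw `dt ~ Exponential(Phi)`; descend the tree with a uniform
`r` to find the leaf whose cumulative sum first exceeds `r·Phi`
(`ceil(log2 N)+1` nodes touched); choose the reaction within that mRNA by a
linear scan of its (short) local list, in list order — a statistically
immaterial tie-break; fire it; and repair only the affected leaves.

Keeping the leaves exact despite pool coupling is the delicate part: every
pool-gated per-mRNA propensity has the form
`k_eff × pool × n_waiting`, so the engine maintains, per gating channel
(30S:PIC, 50S, EF-G:GTP, RF1, RF2, RF3:GTP, RRF, and one channel per tRNA
species), the set of mRNAs with waiting ribosomes and their waiter counts.
When a pool count changes by ±1, exactly the member mRNAs of that channel
receive the propensity delta `k_eff × Δpool × n_waiting` and a leaf
update — no other mRNA is touched, and no approximation or rejection step
is introduced. The fired mRNA itself is recomputed from scratch (its
ribosome configuration changed), as is the global leaf. Floating-point
drift is bounded by a periodic full rebuild (default every 10^4 events) and
audited by a spot check against full recomputation (default every 10^3
events; a relative deviation above 10^-6 aborts the run, and the maximum
observed deviation is reported in the result).

A naive direct-method engine (`engine = "naive"`) re-enumerates every
reaction at every step and selects by one linear scan. It shares the
kinetics code and nothing of the selection machinery, and the test suite
requires the two engines to be statistically indistinguishable (selection
frequencies per locus and per reaction channel, and the distribution of
per-protein elongation times).

All randomness comes from a self-contained xorshift128+ generator seeded
from the user's integer seed; R's RNG is never consulted, and identical
seeds give bit-identical trajectories.

## Rates, pools and units

First-order rates are s^-1. Second-order rates (M^-1 s^-1) are converted to
per-molecule-pair propensity factors `k/(N_A · v)` with the cell volume `v`
in µm³ (default 1.0, the average for exponentially growing cells; within
the physiological range the choice is immaterial). The shipped
`default_rate_table()` holds plausible literature-scale round values —
binding steps at 10^7–10^8 M^-1 s^-1, catalytic sub-steps at
80–250 s^-1, termination/recycling sub-steps tuned fast enough that
maximally initiating mRNAs do not jam at the stop codon, and a lumped
charging rate of 5 s^-1 per deacylated tRNA. They produce a peptide chain
elongation rate C_p around 20 aa/s in a factor-replete matched cell.
Measured rate sets drop in via `read_rate_table()` without code changes;
the catalogue validates completeness and kinetic order.

Factor abundances scale linearly with ribosome count via per-ribosome
ratios (`default_factor_ratios()`): EF-Tu ~8 per ribosome, EF-Ts ~1,
EF-G ~1.5, sub-stoichiometric RFs/RRF, total tRNA ~9 per ribosome. The
perturbation experiments are expressed as multipliers on these ratios
(`scale_pools(..., multipliers = c(EfTu = 2, EfTs = 2))` and so on).

## Transcriptome construction

`codon_usage_from_trnas()` converts tRNA abundances into the codon usage
they can serve: each species' count is split equally among its cognate
codons (a species with 4360 copies decoding two codons contributes 2180 to
each), summed and normalised. `build_transcriptome()` then draws genes from
a length list, samples each ORF's codons i.i.d. from that usage
(amino-acid identity is deliberately ignored; only reading-frame length
and codon bias matter to translation kinetics), assigns copy numbers from
a three-category expression mixture — high with probability 0.05
(zero-truncated Poisson, λ = 6.8), intermediate 0.35 and low 0.60
(zero-truncated geometric, p(k) = (1−λ)^k λ with λ = 0.58 and 0.93) — and
stops once the nucleotide and/or mRNA-count target is crossed. A selected
gene is taken to be expressed, so k = 0 draws are resampled (switchable).
`rebuild_with_usage()` produces mismatch companions: identical genes,
lengths and copy numbers, codons re-sampled under a different usage.

The inverse problem — tRNA abundances whose implied usage matches a given
codon bias — is solved by `trnas_from_codon_usage()` as a nonnegative
least-squares problem on the equal-split linear system. Cross-recognition
(codons decoded by several species) makes the system under-determined, so
the result is one feasible solution; the achieved usage and residual are
always reported rather than silently accepted. The package ships a
representative 42-species tRNA set with standard wobble-rule codon
assignments (`ecoli_trna_map()`) and a matched theoretical abundance table
at three growth rates (`trna_counts_theoretical()`); both are curated
approximations for *E. coli*-like cells, not measured data.

## Observables

* **C_p**, the peptide chain elongation rate: per completed protein,
  decoded amino acids divided by the elongation-phase duration (from 70S
  formation to the translocation exposing the stop codon). Initiation and
  termination dwells are excluded by default (switchable to total dwell).
  Reported as a trailing running mean (window 1000 completions) and as the
  average over the quasi-steady tail (default: completions in the last half
  of simulated time; the first half is burn-in from the empty initial
  condition).
* **Ribosome state fractions**: at each checkpoint every ribosome is
  classified as initiating (still at the start codon, 30S-only or 70S),
  elongating, or terminating, with free 50S and free 30S:PIC tracked
  separately; percentages are relative to total ribosomes, and
  β_r = 100 − %free50S is the activity.
* **Stalling**: an elongating ribosome is stalled when its A site awaits a
  TC whose cognate free-TC count is zero, or when its only forward reaction
  is a sterically blocked translocation. %S is reported both relative to
  elongating ribosomes (the summary-table convention) and to all ribosomes.
  Per decode event, the stalled flag is set when the required resource was
  unavailable at the moment the ribosome became ready (empty cognate TC
  pool at A-site vacancy, or a blocked translocation feeding that codon) —
  an instantaneous, O(1) criterion.
* **Free-TC fractions**: per species, time-averaged
  free-TC/total over the trailing 100 s (configurable), presented sorted
  ascending.
* **Per-codon decode statistics**: mean A-site waiting time (vacancy to
  peptidyl transfer), event count and stall frequency per sense codon.
  The ledger identity (decode events = peptide bonds formed) is asserted in
  the tests.
* **Spacing**: d_r = N_nt/(β_r · N_50) nucleotides per ribosome and
  ρ = 1/d_r, with a warning below the 45-nt physical floor.
* `summarize_runs()` collates replicate simulations into mean ± SD.

## The desk-scale cell

Full-size cells (thousands of mRNAs, ~10^4–10^5 ribosomes, 10^3 simulated
seconds) are out of interactive reach, so the package defines a miniature
with the same *intensive* properties (`desk_cell_system()`): ~35 mRNAs of
mean length 75 aa, 100 ribosomes, pools scaled by the same per-ribosome
ratios, and — crucially — the volume shrunk by `n_ribosomes/15000` so that
every concentration, and hence every bimolecular propensity, matches a
full-size reference cell at roughly one doubling per hour. Simulations run
200 s of cell time in a few seconds.

Two discreteness artifacts of the miniature are handled explicitly and are
design choices of the miniature, not of the model:

* Species whose scaled copy number would fall below 6 molecules are
  excluded (their codons are not used by the synthetic ORFs). A full-size
  cell's rarest isoacceptor still has >100 copies; a miniature that shrinks
  it to one or two molecules exhibits single-server queueing spikes and —
  in polysomes — genuine circular-wait deadlocks (every copy trapped in the
  P site of a ribosome blocked behind a ribosome waiting for that very
  species). These are properties of the miniature, not of the cell.
* The mismatched arm uses a geometric blend (exponent 0.5) between the
  matched abundances and a random permutation of them, which caps the worst
  codon-demand/tRNA-supply ratio near 3 — comparable to the discrepancy
  between measured tRNA pools and wild-type codon usage. A raw permutation
  can oversubscribe a minor species ~15-fold, which jams the miniature
  outright rather than slowing it.

With those guards the five preset arms (matched; mismatched; mismatched
with instant TC recycling; EF-Tu/Ts doubled; all factors, tRNAs and RFs
doubled) run to completion across seeds, and reproduce the qualitative
phenomenology of the full model: mismatch roughly halves C_p and multiplies
stalling several-fold; bypassing TC formation removes the whole mismatch
penalty (confirming the EF-Tu competition mechanism); doubling EF-Tu alone
barely moves C_p while doubling everything in unison raises it
substantially. The miniature is saturated (β_r ≈ 99%, matched %S around
10–25% depending on seed) — denser than a full cell, because short ORFs
put ~4× more initiation sites per nucleotide at maximal initiation — so its
percentages are not quantitative stand-ins for full-scale values; the tests
assert directions and ratios, not absolute levels.

What passing the desk-scale suite does **not** show about real cells: the
synthetic ORFs are i.i.d. codon draws (no codon-order structure, no real
UTRs or initiation-rate variation — all mRNAs initiate maximally), the
tRNA set and its abundances are curated approximations, and the miniature's
state fractions are density-shifted as described. The suite demonstrates
the mechanisms and the exactness of the machinery, not organism-level
numbers.

## Numerical and degenerate-input choices

* Waiting times use `-log1p(-u)/Phi` with `u ∈ [0,1)`; tree descent guards
  the floating-point edge (cumulative target beyond the last positive leaf)
  by falling back to a linear scan.
* `Phi = 0` ends the run with status `"deadlock"` and a report of every
  starved channel (waiters present, pool empty) — never a silent hang.
* Firing a reaction that would drive any count negative is a hard error
  (it would indicate stale propensity bookkeeping), as is a translocation
  fired on a blocked ribosome.
* `t_end = 0` returns the initial state; empty mRNAs offer exactly one
  reaction (PIC binding); mRNAs need at least start + one sense codon +
  stop, internal stops are rejected at construction.
* Integer pools are stored as counts, never concentrations; conservation
  checks are integer-exact at every checkpoint.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on toy cells (1–4 genes, 1–12 ribosomes, up to
a few hundred simulated seconds). The statistical-equivalence check uses
10^5 events per engine on a 4-mRNA toy; the conservation check >10^6 events
on the desk cell; the analytic-limit checks 10^4 waiting-time draws, 200
pure-death replicates, and single-ribosome runs of a few hundred seconds;
the directional experiments one 200-s run per preset arm. The whole suite
completes in well under a minute on one CPU, chosen so the full battery is
run routinely rather than sampled.
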