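// Stochastic translation engine.
//
// One simulated cell holds N mRNA instances (codon-explicit), a pool of
// ribosomal subunits, initiation/elongation/termination/recycling factors and
// per-species tRNA pools.  Reactions local to one mRNA are grouped into a
// per-mRNA propensity sum phi_i; a binary tree over the phi_i (plus one leaf
// for pool-level "global" reactions) supports O(log N) event selection and
// update.  Pool-gated per-mRNA propensities are of the form
// k_eff * pool * n_waiting, so a pool change of +/-1 is propagated exactly to
// the mRNAs that have waiters on that channel, and only to those.
//
// A naive linear-scan direct-method engine (same kinetics, fresh enumeration
// of every reaction each step) is kept as an independent selection path for
// statistical cross-validation.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <string>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xorshift128+ seeded via splitmix64.  Self-contained so trajectories are
// reproducible from the seed alone, independent of R's RNG state.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    auto sm = [&x]() {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // exponential waiting time with total rate `rate`
  double rexp(double rate) { return -std::log1p(-unif()) / rate; }
};

// ---------------------------------------------------------------------------
// Codons: index = 16*b1 + 4*b2 + b3 with A=0, C=1, G=2, U=3.
// ---------------------------------------------------------------------------
static const int COD_UAA = 3 * 16 + 0 * 4 + 0; // 48
static const int COD_UAG = 3 * 16 + 0 * 4 + 2; // 50
static const int COD_UGA = 3 * 16 + 2 * 4 + 0; // 56

static inline bool is_stop(int c) {
  return c == COD_UAA || c == COD_UAG || c == COD_UGA;
}

// ---------------------------------------------------------------------------
// Ribosome phases (ordered walk through initiation, elongation sub-steps,
// termination, recycling).
// ---------------------------------------------------------------------------
enum Phase {
  PH_INIT30S = 0,  // 30S:PIC bound at start codon, awaiting 50S joining
  PH_WAIT_TC,      // 70S, empty A site, awaiting cognate ternary complex
  PH_TC_BOUND,     // TC bound, awaiting GTPase activation/hydrolysis
  PH_ACCING,       // EF-Tu:GDP still bound, aa-tRNA accommodating
  PH_ACCED,        // accommodated, awaiting peptidyl transfer
  PH_PRETRL,       // peptide bond formed, awaiting EF-G:GTP
  PH_EFG,          // EF-G bound, awaiting translocation
  PH_TWRF,         // stop codon in A site, awaiting RF1/RF2
  PH_TRFB,         // RF bound, awaiting peptide release
  PH_TREL,         // peptide released, awaiting RF3-mediated RF dissociation
  PH_TPOST,        // RF gone, awaiting RRF
  PH_TRRF,         // RRF bound, awaiting subunit recycling
  N_PHASE
};

static const char* PHASE_NAMES[N_PHASE] = {
  "init_30S", "await_tc", "tc_bound", "accommodating", "accommodated",
  "pre_translocation", "efg_bound", "await_rf", "rf_bound", "released",
  "post_termination", "rrf_bound"
};

// Minimal P-site separation required BEFORE a forward move (extended footprint
// of 8 codons 5' + P + 6 codons 3'; centre-to-centre minimum 8+6+1).
static const int FOOTPRINT_SEP = 15;

// ---------------------------------------------------------------------------
// Free species pools (tRNA charge-state pools kept in separate arrays).
// ---------------------------------------------------------------------------
enum PoolId {
  P30S = 0,   // free 30S pre-initiation complex (pre-lumped with IFs/fMet-tRNA)
  P50S,
  TU_GTP, TU_GDP, TU_TS, TS_FREE,
  G_GTP, G_GDP,
  PRF1, PRF2, RF3_GTP, RF3_GDP, PRRF,
  N_POOL
};

static const char* POOL_NAMES[N_POOL] = {
  "free_30S_PIC", "free_50S",
  "EfTu_GTP", "EfTu_GDP", "EfTu_Ts", "EfTs_free",
  "EfG_GTP", "EfG_GDP",
  "RF1", "RF2", "RF3_GTP", "RF3_GDP", "RRF"
};

// ---------------------------------------------------------------------------
// Reaction types
// ---------------------------------------------------------------------------
enum ReacType {
  R_PIC = 0, R_JOIN, R_TC, R_GTPASE, R_ACC, R_REJ, R_PEP, R_EFG, R_TRL,
  R_RF1, R_RF2, R_REL, R_RFD, R_RRF, R_REC,
  G_AA, G_TCF, G_TSB, G_TSX, G_GX, G_RF3X,
  N_REAC
};

static const char* REAC_NAMES[N_REAC] = {
  "pic_binding", "subunit_joining", "tc_binding", "gtpase_hydrolysis",
  "accommodation", "tc_rejection", "peptidyl_transfer", "efg_binding",
  "translocation", "rf1_binding", "rf2_binding", "peptide_release",
  "rf_dissociation", "rrf_binding", "recycling",
  "aminoacylation", "tc_formation", "efts_binding", "efts_exchange",
  "efg_exchange", "rf3_exchange"
};

// Effective rate constants (second-order ones already divided by N_A * v).
struct Rates {
  double pic, join, tc, gtpase, acc, rej, pep, efg, trl,
         rf, rel, rfd, rrf, rec,
         aa, tcf, tsb, tsx, gx, rf3x;
};

// Pool-gated waiting channels for per-mRNA reactions.
enum ChanId {
  CH_PIC = 0, CH_50S, CH_EFG, CH_RF1, CH_RF2, CH_RF3, CH_RRF,
  N_CHAN_FIXED
  // CH_TC + t for tRNA species t follows
};

struct Rib {
  int phase;
  int p;        // P-site codon index, 0-based (0 = start codon)
  int a_trna;   // tRNA species in A site (-1 none)
  int p_trna;   // tRNA species in P site (-1 none, -2 initiator)
  int rf;       // release factor bound (0 none, 1, 2)
  double t_init, t_eb, t_ee, t_wait;
  bool dwell_stalled;  // current A-site dwell began with zero cognate free TC
  bool stall_pending;  // translocation into this codon was sterically blocked
};

struct MRna {
  int gene;              // gene index, 0-based
  std::vector<Rib> ribs; // sorted by p DESCENDING (leader first)
};

struct Reaction {
  int type;
  int mrna;   // -1 for global
  int rib;    // index into mrnas[mrna].ribs, -1 for mRNA-level / global
  int trna;   // tRNA species for R_TC / G_AA / G_TCF, else -1
  double prop;
};

struct System {
  int n_gene, n_trna, N; // N = number of mRNA instances
  std::vector<std::vector<int> > gene_codons;   // incl. start + stop
  std::vector<int> mrna_gene;                   // length N
  std::vector<std::vector<int> > trna_codons;   // cognate codons per tRNA
  std::vector<std::vector<int> > codon_trnas;   // decoding tRNAs per codon (64)
  std::vector<std::string> trna_names, gene_names;
  Rates k;
  bool instant_tc; // ejected tRNAs return straight to free TC; charging,
                   // TC formation and the EF-Tu/Ts cycle are bypassed
};

struct Delta { int pool; long d; }; // pool < 0 encodes free_TC[-pool-1]

struct State {
  double t;
  std::vector<long> pools;            // N_POOL
  std::vector<long> deacyl, charged, ftc; // per tRNA species
  std::vector<MRna> mrnas;
  // event tallies: rows = mRNAs plus one global row, cols = reaction types
  std::vector<double> evt;
  double dt_sum, dt_sumsq;
  // records
  std::vector<int> cmp_gene, cmp_len;
  std::vector<double> cmp_tinit, cmp_teb, cmp_tee, cmp_trel;
  std::vector<double> dec_count, dec_wait, dec_stall; // per codon (64)
  // optional raw decode log
  bool keep_log; size_t log_cap;
  std::vector<int> log_codon, log_trna; std::vector<double> log_wait, log_t;
  std::vector<int> log_stall;
  State() : t(0.0), dt_sum(0.0), dt_sumsq(0.0), keep_log(false), log_cap(0) {}
};

// ---------------------------------------------------------------------------
// small helpers
// ---------------------------------------------------------------------------
static inline void dec_pool(long& x, const char* what) {
  if (--x < 0) stop("reaction fired would drive count of %s negative (stale propensity bookkeeping)", what);
}

static inline bool blocked_rib(const MRna& m, int j) {
  // ribs sorted by p descending; j's downstream neighbour is j-1
  return j > 0 && (m.ribs[j - 1].p - m.ribs[j].p) < FOOTPRINT_SEP;
}

static inline bool start_clear(const MRna& m) {
  // incoming 30S:PIC would sit with P site at codon 0
  return m.ribs.empty() || (m.ribs.back().p - 0) >= FOOTPRINT_SEP;
}

static inline long cognate_ftc_total(const System& S, const State& st, int codon) {
  long tot = 0;
  for (size_t q = 0; q < S.codon_trnas[codon].size(); ++q)
    tot += st.ftc[S.codon_trnas[codon][q]];
  return tot;
}

// ---------------------------------------------------------------------------
// Reaction enumeration (shared by both engines and by the R-level inspector)
// ---------------------------------------------------------------------------
static void enumerate_local(const System& S, const State& st, int i,
                            std::vector<Reaction>& out) {
  const MRna& m = st.mrnas[i];
  const std::vector<int>& cod = S.gene_codons[m.gene];
  if (start_clear(m) && st.pools[P30S] > 0 && S.k.pic > 0) {
    Reaction r = { R_PIC, i, -1, -1, S.k.pic * st.pools[P30S] };
    out.push_back(r);
  }
  for (int j = 0; j < (int)m.ribs.size(); ++j) {
    const Rib& rb = m.ribs[j];
    switch (rb.phase) {
    case PH_INIT30S:
      if (st.pools[P50S] > 0) {
        Reaction r = { R_JOIN, i, j, -1, S.k.join * st.pools[P50S] };
        out.push_back(r);
      }
      break;
    case PH_WAIT_TC: {
      int c = cod[rb.p + 1];
      const std::vector<int>& ts = S.codon_trnas[c];
      for (size_t q = 0; q < ts.size(); ++q) {
        if (st.ftc[ts[q]] > 0) {
          Reaction r = { R_TC, i, j, ts[q], S.k.tc * st.ftc[ts[q]] };
          out.push_back(r);
        }
      }
      break;
    }
    case PH_TC_BOUND: {
      Reaction r = { R_GTPASE, i, j, -1, S.k.gtpase };
      out.push_back(r);
      break;
    }
    case PH_ACCING: {
      Reaction r = { R_ACC, i, j, -1, S.k.acc };
      out.push_back(r);
      if (S.k.rej > 0) {
        Reaction r2 = { R_REJ, i, j, -1, S.k.rej };
        out.push_back(r2);
      }
      break;
    }
    case PH_ACCED: {
      Reaction r = { R_PEP, i, j, -1, S.k.pep };
      out.push_back(r);
      break;
    }
    case PH_PRETRL:
      if (st.pools[G_GTP] > 0) {
        Reaction r = { R_EFG, i, j, -1, S.k.efg * st.pools[G_GTP] };
        out.push_back(r);
      }
      break;
    case PH_EFG:
      if (!blocked_rib(m, j)) {
        Reaction r = { R_TRL, i, j, -1, S.k.trl };
        out.push_back(r);
      }
      break;
    case PH_TWRF: {
      int c = cod[rb.p + 1];
      if ((c == COD_UAA || c == COD_UAG) && st.pools[PRF1] > 0) {
        Reaction r = { R_RF1, i, j, -1, S.k.rf * st.pools[PRF1] };
        out.push_back(r);
      }
      if ((c == COD_UAA || c == COD_UGA) && st.pools[PRF2] > 0) {
        Reaction r = { R_RF2, i, j, -1, S.k.rf * st.pools[PRF2] };
        out.push_back(r);
      }
      break;
    }
    case PH_TRFB: {
      Reaction r = { R_REL, i, j, -1, S.k.rel };
      out.push_back(r);
      break;
    }
    case PH_TREL:
      if (st.pools[RF3_GTP] > 0) {
        Reaction r = { R_RFD, i, j, -1, S.k.rfd * st.pools[RF3_GTP] };
        out.push_back(r);
      }
      break;
    case PH_TPOST:
      if (st.pools[PRRF] > 0) {
        Reaction r = { R_RRF, i, j, -1, S.k.rrf * st.pools[PRRF] };
        out.push_back(r);
      }
      break;
    case PH_TRRF: {
      Reaction r = { R_REC, i, j, -1, S.k.rec };
      out.push_back(r);
      break;
    }
    default:
      stop("internal: unknown ribosome phase");
    }
  }
}

static void enumerate_global(const System& S, const State& st,
                             std::vector<Reaction>& out) {
  if (!S.instant_tc) {
    for (int t = 0; t < S.n_trna; ++t) {
      if (st.deacyl[t] > 0) {
        Reaction r = { G_AA, -1, -1, t, S.k.aa * st.deacyl[t] };
        out.push_back(r);
      }
      if (st.charged[t] > 0 && st.pools[TU_GTP] > 0) {
        Reaction r = { G_TCF, -1, -1, t,
                       S.k.tcf * (double)st.charged[t] * (double)st.pools[TU_GTP] };
        out.push_back(r);
      }
    }
    if (st.pools[TU_GDP] > 0 && st.pools[TS_FREE] > 0) {
      Reaction r = { G_TSB, -1, -1, -1,
                     S.k.tsb * (double)st.pools[TU_GDP] * (double)st.pools[TS_FREE] };
      out.push_back(r);
    }
    if (st.pools[TU_TS] > 0) {
      Reaction r = { G_TSX, -1, -1, -1, S.k.tsx * st.pools[TU_TS] };
      out.push_back(r);
    }
  }
  if (st.pools[G_GDP] > 0) {
    Reaction r = { G_GX, -1, -1, -1, S.k.gx * st.pools[G_GDP] };
    out.push_back(r);
  }
  if (st.pools[RF3_GDP] > 0) {
    Reaction r = { G_RF3X, -1, -1, -1, S.k.rf3x * st.pools[RF3_GDP] };
    out.push_back(r);
  }
}

// ---------------------------------------------------------------------------
// Firing (pure stoichiometry + phase advance + record emission).
// Pool changes are appended to `deltas` so the tree engine can propagate them.
// ---------------------------------------------------------------------------
static void release_trna(const System& S, State& st, int t,
                         std::vector<Delta>& deltas) {
  if (t == -2) return; // initiator: part of the lumped 30S:PIC
  if (t < 0) return;
  if (S.instant_tc) {
    st.ftc[t] += 1;
    Delta d = { -t - 1, +1 }; deltas.push_back(d);
  } else {
    st.deacyl[t] += 1; // not channel-gated; no per-mRNA delta needed
  }
}

static void record_decode(const System& S, State& st, int codon, int trna,
                          double wait, bool stalled) {
  st.dec_count[codon] += 1;
  st.dec_wait[codon] += wait;
  if (stalled) st.dec_stall[codon] += 1;
  if (st.keep_log && st.log_codon.size() < st.log_cap) {
    st.log_codon.push_back(codon); st.log_trna.push_back(trna);
    st.log_wait.push_back(wait); st.log_t.push_back(st.t);
    st.log_stall.push_back(stalled ? 1 : 0);
  }
}

// enter await_tc (or await_rf if a stop codon is exposed)
static void enter_wait(const System& S, State& st, MRna& m, Rib& rb) {
  const std::vector<int>& cod = S.gene_codons[m.gene];
  int c = cod[rb.p + 1];
  if (is_stop(c)) {
    rb.phase = PH_TWRF;
    rb.t_ee = st.t;
  } else {
    rb.phase = PH_WAIT_TC;
    rb.t_wait = st.t;
    rb.dwell_stalled = (cognate_ftc_total(S, st, c) == 0);
  }
}

static void apply_reaction(const System& S, State& st, const Reaction& rx,
                           std::vector<Delta>& deltas) {
  if (rx.mrna < 0) { // global
    int t = rx.trna;
    switch (rx.type) {
    case G_AA:
      dec_pool(st.deacyl[t], "deacylated tRNA");
      st.charged[t] += 1;
      break;
    case G_TCF: {
      dec_pool(st.charged[t], "charged tRNA");
      dec_pool(st.pools[TU_GTP], POOL_NAMES[TU_GTP]);
      st.ftc[t] += 1;
      Delta d = { -t - 1, +1 }; deltas.push_back(d);
      break;
    }
    case G_TSB:
      dec_pool(st.pools[TU_GDP], POOL_NAMES[TU_GDP]);
      dec_pool(st.pools[TS_FREE], POOL_NAMES[TS_FREE]);
      st.pools[TU_TS] += 1;
      break;
    case G_TSX:
      dec_pool(st.pools[TU_TS], POOL_NAMES[TU_TS]);
      st.pools[TU_GTP] += 1;
      st.pools[TS_FREE] += 1;
      break;
    case G_GX: {
      dec_pool(st.pools[G_GDP], POOL_NAMES[G_GDP]);
      st.pools[G_GTP] += 1;
      Delta d = { G_GTP, +1 }; deltas.push_back(d);
      break;
    }
    case G_RF3X: {
      dec_pool(st.pools[RF3_GDP], POOL_NAMES[RF3_GDP]);
      st.pools[RF3_GTP] += 1;
      Delta d = { RF3_GTP, +1 }; deltas.push_back(d);
      break;
    }
    default:
      stop("internal: bad global reaction");
    }
    return;
  }

  MRna& m = st.mrnas[rx.mrna];
  switch (rx.type) {
  case R_PIC: {
    dec_pool(st.pools[P30S], POOL_NAMES[P30S]);
    Delta d = { P30S, -1 }; deltas.push_back(d);
    Rib rb;
    rb.phase = PH_INIT30S; rb.p = 0; rb.a_trna = -1; rb.p_trna = -2; rb.rf = 0;
    rb.t_init = st.t; rb.t_eb = 0; rb.t_ee = 0; rb.t_wait = 0;
    rb.dwell_stalled = false; rb.stall_pending = false;
    m.ribs.push_back(rb); // p = 0 is minimal: descending order preserved
    break;
  }
  case R_JOIN: {
    dec_pool(st.pools[P50S], POOL_NAMES[P50S]);
    Delta d = { P50S, -1 }; deltas.push_back(d);
    Rib& rb = m.ribs[rx.rib];
    rb.t_eb = st.t;
    enter_wait(S, st, m, rb);
    break;
  }
  case R_TC: {
    dec_pool(st.ftc[rx.trna], "tRNA in free TC");
    Delta d = { -rx.trna - 1, -1 }; deltas.push_back(d);
    Rib& rb = m.ribs[rx.rib];
    rb.a_trna = rx.trna;
    rb.phase = PH_TC_BOUND;
    break;
  }
  case R_GTPASE:
    m.ribs[rx.rib].phase = PH_ACCING;
    break;
  case R_ACC: {
    Rib& rb = m.ribs[rx.rib];
    if (!S.instant_tc) st.pools[TU_GDP] += 1; // EF-Tu:GDP leaves the ribosome
    rb.phase = PH_ACCED;
    break;
  }
  case R_REJ: {
    Rib& rb = m.ribs[rx.rib];
    int t = rb.a_trna;
    if (S.instant_tc) {
      st.ftc[t] += 1;
      Delta d = { -t - 1, +1 }; deltas.push_back(d);
    } else {
      st.charged[t] += 1; // aa-tRNA leaves still charged
      st.pools[TU_GDP] += 1;
    }
    rb.a_trna = -1;
    // dwell continues: t_wait (and any stall mark) kept
    rb.phase = PH_WAIT_TC;
    break;
  }
  case R_PEP: {
    Rib& rb = m.ribs[rx.rib];
    int codon = S.gene_codons[m.gene][rb.p + 1];
    record_decode(S, st, codon, rb.a_trna, st.t - rb.t_wait,
                  rb.dwell_stalled || rb.stall_pending);
    rb.dwell_stalled = false; rb.stall_pending = false;
    rb.phase = PH_PRETRL;
    break;
  }
  case R_EFG: {
    dec_pool(st.pools[G_GTP], POOL_NAMES[G_GTP]);
    Delta d = { G_GTP, -1 }; deltas.push_back(d);
    Rib& rb = m.ribs[rx.rib];
    rb.phase = PH_EFG;
    if (blocked_rib(m, rx.rib)) rb.stall_pending = true;
    break;
  }
  case R_TRL: {
    Rib& rb = m.ribs[rx.rib];
    if (blocked_rib(m, rx.rib))
      stop("translocation fired on a sterically blocked ribosome");
    release_trna(S, st, rb.p_trna, deltas); // E-site release
    st.pools[G_GDP] += 1;
    rb.p += 1;
    rb.p_trna = rb.a_trna;
    rb.a_trna = -1;
    enter_wait(S, st, m, rb);
    break;
  }
  case R_RF1: {
    dec_pool(st.pools[PRF1], POOL_NAMES[PRF1]);
    Delta d = { PRF1, -1 }; deltas.push_back(d);
    Rib& rb = m.ribs[rx.rib];
    rb.rf = 1; rb.phase = PH_TRFB;
    break;
  }
  case R_RF2: {
    dec_pool(st.pools[PRF2], POOL_NAMES[PRF2]);
    Delta d = { PRF2, -1 }; deltas.push_back(d);
    Rib& rb = m.ribs[rx.rib];
    rb.rf = 2; rb.phase = PH_TRFB;
    break;
  }
  case R_REL: {
    Rib& rb = m.ribs[rx.rib];
    // protein completed: length in decoded amino acids (sense codons after AUG)
    int len = (int)S.gene_codons[m.gene].size() - 2;
    st.cmp_gene.push_back(m.gene);
    st.cmp_len.push_back(len);
    st.cmp_tinit.push_back(rb.t_init);
    st.cmp_teb.push_back(rb.t_eb);
    st.cmp_tee.push_back(rb.t_ee);
    st.cmp_trel.push_back(st.t);
    rb.phase = PH_TREL;
    break;
  }
  case R_RFD: {
    dec_pool(st.pools[RF3_GTP], POOL_NAMES[RF3_GTP]);
    st.pools[RF3_GDP] += 1;
    Delta d = { RF3_GTP, -1 }; deltas.push_back(d);
    Rib& rb = m.ribs[rx.rib];
    if (rb.rf == 1) { st.pools[PRF1] += 1; Delta d2 = { PRF1, +1 }; deltas.push_back(d2); }
    else            { st.pools[PRF2] += 1; Delta d2 = { PRF2, +1 }; deltas.push_back(d2); }
    rb.rf = 0; rb.phase = PH_TPOST;
    break;
  }
  case R_RRF: {
    dec_pool(st.pools[PRRF], POOL_NAMES[PRRF]);
    Delta d = { PRRF, -1 }; deltas.push_back(d);
    m.ribs[rx.rib].phase = PH_TRRF;
    break;
  }
  case R_REC: {
    Rib rb = m.ribs[rx.rib];
    release_trna(S, st, rb.p_trna, deltas);
    st.pools[PRRF] += 1; st.pools[P50S] += 1; st.pools[P30S] += 1;
    Delta d1 = { PRRF, +1 }; deltas.push_back(d1);
    Delta d2 = { P50S, +1 }; deltas.push_back(d2);
    Delta d3 = { P30S, +1 }; deltas.push_back(d3);
    m.ribs.erase(m.ribs.begin() + rx.rib);
    break;
  }
  default:
    stop("internal: bad local reaction");
  }
}

// ---------------------------------------------------------------------------
// Propensity tree (flat array, power-of-two padded; root at node 1).
// ---------------------------------------------------------------------------
struct Tree {
  int L, P; // leaves used, padded size
  std::vector<double> node; // size 2P
  void init(int leaves) {
    L = leaves;
    P = 1; while (P < L) P <<= 1;
    node.assign(2 * (size_t)P, 0.0);
  }
  double root() const { return node[1]; }
  int set(int leaf, double v) { // returns touched node count
    int idx = P + leaf;
    node[idx] = v;
    int touched = 1;
    for (idx >>= 1; idx >= 1; idx >>= 1) {
      node[idx] = node[2 * idx] + node[2 * idx + 1];
      ++touched;
    }
    return touched;
  }
  int select(double r) const {
    double x = r * node[1];
    int v = 1;
    while (v < P) {
      if (x < node[2 * v]) v = 2 * v;
      else { x -= node[2 * v]; v = 2 * v + 1; }
    }
    int leaf = v - P;
    if (leaf >= L || node[v] <= 0.0) {
      // floating-point edge: fall back to a linear scan for the last
      // positive leaf not beyond the cumulative target
      double acc = 0.0, target = r * node[1];
      int last_pos = -1;
      for (int i = 0; i < L; ++i) {
        double w = node[P + i];
        if (w > 0.0) {
          last_pos = i;
          acc += w;
          if (acc > target) return i;
        }
      }
      if (last_pos >= 0) return last_pos;
      stop("select on an empty propensity tree");
    }
    return leaf;
  }
};

// ---------------------------------------------------------------------------
// Tree engine bookkeeping: per-mRNA channel waiter counts + channel member
// sets, maintained so phi_i can be delta-updated exactly on pool changes.
// ---------------------------------------------------------------------------
struct Book {
  int N, n_chan; // n_chan = N_CHAN_FIXED + n_trna
  std::vector<int> W;               // N x n_chan, row-major
  std::vector<std::set<int> > mem;  // per channel: mRNAs with W > 0
  std::vector<double> kchan;        // per channel effective rate constant
  std::vector<double> phi;          // maintained per-mRNA propensity sums
  Tree tree;

  long chan_pool(const System& S, const State& st, int c) const {
    switch (c) {
    case CH_PIC: return st.pools[P30S];
    case CH_50S: return st.pools[P50S];
    case CH_EFG: return st.pools[G_GTP];
    case CH_RF1: return st.pools[PRF1];
    case CH_RF2: return st.pools[PRF2];
    case CH_RF3: return st.pools[RF3_GTP];
    case CH_RRF: return st.pools[PRRF];
    default:     return st.ftc[c - N_CHAN_FIXED];
    }
  }

  void init(const System& S, const State& st) {
    N = S.N;
    n_chan = N_CHAN_FIXED + S.n_trna;
    W.assign((size_t)N * n_chan, 0);
    mem.assign(n_chan, std::set<int>());
    kchan.assign(n_chan, 0.0);
    kchan[CH_PIC] = S.k.pic; kchan[CH_50S] = S.k.join; kchan[CH_EFG] = S.k.efg;
    kchan[CH_RF1] = S.k.rf;  kchan[CH_RF2] = S.k.rf;   kchan[CH_RF3] = S.k.rfd;
    kchan[CH_RRF] = S.k.rrf;
    for (int t = 0; t < S.n_trna; ++t) kchan[N_CHAN_FIXED + t] = S.k.tc;
    phi.assign(N, 0.0);
    tree.init(N + 1); // + global leaf
    for (int i = 0; i < N; ++i) recompute_mrna(S, st, i);
    recompute_global(S, st);
  }

  // exact phi_i from current waiter counts and pools + first-order terms
  void recompute_mrna(const System& S, const State& st, int i) {
    const MRna& m = st.mrnas[i];
    const std::vector<int>& cod = S.gene_codons[m.gene];
    // new waiter counts for this mRNA
    static thread_local std::vector<int> wnew;
    wnew.assign(n_chan, 0);
    double first = 0.0;
    if (start_clear(m)) wnew[CH_PIC] = 1;
    for (int j = 0; j < (int)m.ribs.size(); ++j) {
      const Rib& rb = m.ribs[j];
      switch (rb.phase) {
      case PH_INIT30S: wnew[CH_50S] += 1; break;
      case PH_WAIT_TC: {
        const std::vector<int>& ts = S.codon_trnas[cod[rb.p + 1]];
        for (size_t q = 0; q < ts.size(); ++q) wnew[N_CHAN_FIXED + ts[q]] += 1;
        break;
      }
      case PH_TC_BOUND: first += S.k.gtpase; break;
      case PH_ACCING:   first += S.k.acc + S.k.rej; break;
      case PH_ACCED:    first += S.k.pep; break;
      case PH_PRETRL:   wnew[CH_EFG] += 1; break;
      case PH_EFG:      if (!blocked_rib(m, j)) first += S.k.trl; break;
      case PH_TWRF: {
        int c = cod[rb.p + 1];
        if (c == COD_UAA || c == COD_UAG) wnew[CH_RF1] += 1;
        if (c == COD_UAA || c == COD_UGA) wnew[CH_RF2] += 1;
        break;
      }
      case PH_TRFB:  first += S.k.rel; break;
      case PH_TREL:  wnew[CH_RF3] += 1; break;
      case PH_TPOST: wnew[CH_RRF] += 1; break;
      case PH_TRRF:  first += S.k.rec; break;
      }
    }
    double p = first;
    int* wrow = &W[(size_t)i * n_chan];
    for (int c = 0; c < n_chan; ++c) {
      int nw = wnew[c];
      if (nw != wrow[c]) {
        if (nw > 0 && wrow[c] == 0) mem[c].insert(i);
        else if (nw == 0 && wrow[c] > 0) mem[c].erase(i);
        wrow[c] = nw;
      }
      if (nw > 0) p += kchan[c] * (double)chan_pool(S, st, c) * nw;
    }
    phi[i] = p;
    tree.set(i, p);
  }

  void recompute_global(const System& S, const State& st) {
    double g = 0.0;
    if (!S.instant_tc) {
      for (int t = 0; t < S.n_trna; ++t) {
        g += S.k.aa * (double)st.deacyl[t];
        g += S.k.tcf * (double)st.charged[t] * (double)st.pools[TU_GTP];
      }
      g += S.k.tsb * (double)st.pools[TU_GDP] * (double)st.pools[TS_FREE];
      g += S.k.tsx * (double)st.pools[TU_TS];
    }
    g += S.k.gx * (double)st.pools[G_GDP];
    g += S.k.rf3x * (double)st.pools[RF3_GDP];
    tree.set(N, g);
  }

  // propagate a +/-delta on a gating pool to every OTHER mRNA with waiters
  void pool_delta(const System& S, const State& st, const Delta& d, int skip) {
    int c;
    if (d.pool < 0) c = N_CHAN_FIXED + (-d.pool - 1);
    else switch (d.pool) {
      case P30S: c = CH_PIC; break;
      case P50S: c = CH_50S; break;
      case G_GTP: c = CH_EFG; break;
      case PRF1: c = CH_RF1; break;
      case PRF2: c = CH_RF2; break;
      case RF3_GTP: c = CH_RF3; break;
      case PRRF: c = CH_RRF; break;
      default: return; // pool does not gate any per-mRNA channel
    }
    double kd = kchan[c] * (double)d.d;
    for (std::set<int>::const_iterator it = mem[c].begin(); it != mem[c].end(); ++it) {
      int j = *it;
      if (j == skip) continue;
      phi[j] += kd * W[(size_t)j * n_chan + c];
      if (phi[j] < 0 && phi[j] > -1e-9) phi[j] = 0.0;
      tree.set(j, phi[j]);
    }
  }
};

// ---------------------------------------------------------------------------
// Conservation totals (independent full-state scan)
// ---------------------------------------------------------------------------
static void totals_scan(const System& S, const State& st,
                        std::vector<double>& fixed, std::vector<double>& trna) {
  // fixed: 30S, 50S, EfTu, EfTs, EfG, RF1, RF2, RF3, RRF, mRNAs
  fixed.assign(10, 0.0);
  trna.assign(S.n_trna, 0.0);
  fixed[0] = st.pools[P30S];
  fixed[1] = st.pools[P50S];
  fixed[2] = st.pools[TU_GTP] + st.pools[TU_GDP] + st.pools[TU_TS];
  fixed[3] = st.pools[TS_FREE] + st.pools[TU_TS];
  fixed[4] = st.pools[G_GTP] + st.pools[G_GDP];
  fixed[5] = st.pools[PRF1];
  fixed[6] = st.pools[PRF2];
  fixed[7] = st.pools[RF3_GTP] + st.pools[RF3_GDP];
  fixed[8] = st.pools[PRRF];
  fixed[9] = st.mrnas.size();
  for (int t = 0; t < S.n_trna; ++t) {
    trna[t] = st.deacyl[t] + st.charged[t] + st.ftc[t];
    if (!S.instant_tc) fixed[2] += st.ftc[t]; // free TC carries one EF-Tu
  }
  for (size_t i = 0; i < st.mrnas.size(); ++i) {
    const MRna& m = st.mrnas[i];
    for (size_t j = 0; j < m.ribs.size(); ++j) {
      const Rib& rb = m.ribs[j];
      fixed[0] += 1;
      if (rb.phase != PH_INIT30S) fixed[1] += 1;
      if (!S.instant_tc && (rb.phase == PH_TC_BOUND || rb.phase == PH_ACCING))
        fixed[2] += 1; // EF-Tu still on the ribosome
      if (rb.phase == PH_EFG) fixed[4] += 1;
      if (rb.rf == 1) fixed[5] += 1;
      if (rb.rf == 2) fixed[6] += 1;
      if (rb.phase == PH_TRRF) fixed[8] += 1;
      if (rb.a_trna >= 0) trna[rb.a_trna] += 1;
      if (rb.p_trna >= 0) trna[rb.p_trna] += 1;
    }
  }
}

// ---------------------------------------------------------------------------
// Checkpoint observer
// ---------------------------------------------------------------------------
struct Observer {
  std::vector<double> t;
  std::vector<int> n_free50, n_free30, n_init, n_elong, n_term, n_stalled, n_bound;
  std::vector<std::vector<double> > ftc_rows, pool_rows, tot_fixed_rows, tot_trna_rows;

  void record(const System& S, const State& st) {
    t.push_back(st.t);
    int ninit = 0, nel = 0, nterm = 0, nst = 0, nb = 0;
    for (size_t i = 0; i < st.mrnas.size(); ++i) {
      const MRna& m = st.mrnas[i];
      const std::vector<int>& cod = S.gene_codons[m.gene];
      for (size_t j = 0; j < m.ribs.size(); ++j) {
        const Rib& rb = m.ribs[j];
        ++nb;
        if (rb.phase >= PH_TWRF) { ++nterm; continue; }
        if (rb.p == 0) { ++ninit; continue; } // still at the start codon
        ++nel;
        bool stalled = false;
        if (rb.phase == PH_WAIT_TC &&
            cognate_ftc_total(S, st, cod[rb.p + 1]) == 0) stalled = true;
        if (rb.phase == PH_EFG && blocked_rib(m, (int)j)) stalled = true;
        if (stalled) ++nst;
      }
    }
    n_free50.push_back((int)st.pools[P50S]);
    n_free30.push_back((int)st.pools[P30S]);
    n_init.push_back(ninit); n_elong.push_back(nel);
    n_term.push_back(nterm); n_stalled.push_back(nst); n_bound.push_back(nb);
    std::vector<double> fr(st.ftc.begin(), st.ftc.end());
    ftc_rows.push_back(fr);
    std::vector<double> pr(st.pools.begin(), st.pools.end());
    pool_rows.push_back(pr);
    std::vector<double> tf, tt;
    totals_scan(S, st, tf, tt);
    tot_fixed_rows.push_back(tf);
    tot_trna_rows.push_back(tt);
  }
};

// ---------------------------------------------------------------------------
// Parsing the R-side system / state lists
// ---------------------------------------------------------------------------
static System parse_system(List sys) {
  System S;
  List gc = sys["gene_codons"];
  S.n_gene = gc.size();
  S.gene_codons.resize(S.n_gene);
  CharacterVector gn = sys["gene_names"];
  for (int g = 0; g < S.n_gene; ++g) {
    IntegerVector v = gc[g];
    S.gene_codons[g] = std::vector<int>(v.begin(), v.end());
    if (S.gene_codons[g].size() < 3)
      stop("gene '%s': an mRNA needs at least start + 1 sense codon + stop",
           std::string(gn[g]).c_str());
    if (!is_stop(S.gene_codons[g].back()))
      stop("gene '%s' does not end with a stop codon", std::string(gn[g]).c_str());
    for (size_t q = 0; q + 1 < S.gene_codons[g].size(); ++q)
      if (is_stop(S.gene_codons[g][q]))
        stop("gene '%s' has an internal stop codon", std::string(gn[g]).c_str());
    S.gene_names.push_back(std::string(gn[g]));
  }
  IntegerVector mg = sys["mrna_gene"];
  S.N = mg.size();
  for (int i = 0; i < S.N; ++i) {
    int g = mg[i] - 1;
    if (g < 0 || g >= S.n_gene) stop("mrna_gene index out of range");
    S.mrna_gene.push_back(g);
  }
  List tc = sys["trna_codons"];
  CharacterVector tn = sys["trna_names"];
  S.n_trna = tc.size();
  S.trna_codons.resize(S.n_trna);
  S.codon_trnas.assign(64, std::vector<int>());
  for (int t = 0; t < S.n_trna; ++t) {
    IntegerVector v = tc[t];
    S.trna_codons[t] = std::vector<int>(v.begin(), v.end());
    for (int q = 0; q < v.size(); ++q) {
      if (v[q] < 0 || v[q] > 63) stop("codon code out of range in decode map");
      S.codon_trnas[v[q]].push_back(t);
    }
    S.trna_names.push_back(std::string(tn[t]));
  }
  // every sense codon used by some gene must be decodable
  for (int g = 0; g < S.n_gene; ++g)
    for (size_t q = 1; q + 1 < S.gene_codons[g].size(); ++q)
      if (S.codon_trnas[S.gene_codons[g][q]].empty())
        stop("codon code %d in gene '%s' is decoded by no tRNA species",
             S.gene_codons[g][q], S.gene_names[g].c_str());

  NumericVector rv = sys["rates_eff"];
  CharacterVector rn = rv.names();
  std::map<std::string, double> rm;
  for (int q = 0; q < rv.size(); ++q) rm[std::string(rn[q])] = rv[q];
  auto need = [&rm](const char* nm) {
    std::map<std::string, double>::iterator it = rm.find(nm);
    if (it == rm.end()) stop("missing rate entry for reaction '%s'", nm);
    if (it->second < 0) stop("negative rate for reaction '%s'", nm);
    return it->second;
  };
  S.k.pic = need("pic_binding");       S.k.join = need("subunit_joining");
  S.k.tc = need("tc_binding");         S.k.gtpase = need("gtpase_hydrolysis");
  S.k.acc = need("accommodation");     S.k.rej = need("tc_rejection");
  S.k.pep = need("peptidyl_transfer"); S.k.efg = need("efg_binding");
  S.k.trl = need("translocation");     S.k.rf = need("rf_binding");
  S.k.rel = need("peptide_release");   S.k.rfd = need("rf_dissociation");
  S.k.rrf = need("rrf_binding");       S.k.rec = need("recycling");
  S.k.aa = need("aminoacylation");     S.k.tcf = need("tc_formation");
  S.k.tsb = need("efts_binding");      S.k.tsx = need("efts_exchange");
  S.k.gx = need("efg_exchange");       S.k.rf3x = need("rf3_exchange");
  S.instant_tc = as<bool>(sys["instant_tc"]);
  return S;
}

static int phase_from_string(const std::string& s) {
  for (int p = 0; p < N_PHASE; ++p)
    if (s == PHASE_NAMES[p]) return p;
  stop("unknown ribosome phase '%s'", s.c_str());
  return -1;
}

static int trna_index(const System& S, const std::string& nm) {
  if (nm == "" || nm == "NA") return -1;
  if (nm == "initiator") return -2;
  for (int t = 0; t < S.n_trna; ++t)
    if (S.trna_names[t] == nm) return t;
  stop("unknown tRNA species '%s'", nm.c_str());
  return -1;
}

static State parse_state(const System& S, List state) {
  State st;
  st.pools.assign(N_POOL, 0);
  NumericVector pv = state["pools"];
  CharacterVector pn = pv.names();
  std::map<std::string, long> pm;
  for (int q = 0; q < pv.size(); ++q) {
    if (pv[q] < 0) stop("negative pool count for %s", std::string(pn[q]).c_str());
    pm[std::string(pn[q])] = (long)(pv[q] + 0.5);
  }
  for (int p = 0; p < N_POOL; ++p) {
    std::map<std::string, long>::iterator it = pm.find(POOL_NAMES[p]);
    if (it == pm.end()) stop("missing species count for %s", POOL_NAMES[p]);
    st.pools[p] = it->second;
  }
  NumericVector da = state["deacylated"], ch = state["charged"], ft = state["free_tc"];
  if (da.size() != S.n_trna || ch.size() != S.n_trna || ft.size() != S.n_trna)
    stop("tRNA pool vectors must have one entry per tRNA species");
  st.deacyl.resize(S.n_trna); st.charged.resize(S.n_trna); st.ftc.resize(S.n_trna);
  for (int t = 0; t < S.n_trna; ++t) {
    if (da[t] < 0 || ch[t] < 0 || ft[t] < 0) stop("negative tRNA pool count");
    st.deacyl[t] = (long)(da[t] + 0.5);
    st.charged[t] = (long)(ch[t] + 0.5);
    st.ftc[t] = (long)(ft[t] + 0.5);
  }
  st.mrnas.resize(S.N);
  for (int i = 0; i < S.N; ++i) st.mrnas[i].gene = S.mrna_gene[i];
  if (state.containsElementNamed("ribosomes")) {
    List rl = state["ribosomes"];
    if (rl.size() > 0 && rl.size() != S.N)
      stop("`ribosomes` must have one entry per mRNA instance");
    for (int i = 0; i < rl.size(); ++i) {
      if (Rf_isNull(rl[i])) continue;
      DataFrame df = as<DataFrame>(rl[i]);
      CharacterVector ph = df["phase"];
      IntegerVector ps = df["p_site"];
      CharacterVector at = df["a_trna"], pt = df["p_trna"];
      IntegerVector rf = df["rf"];
      int L = (int)S.gene_codons[S.mrna_gene[i]].size();
      std::vector<Rib> ribs;
      for (int r = 0; r < df.nrows(); ++r) {
        Rib rb;
        rb.phase = phase_from_string(std::string(ph[r]));
        rb.p = ps[r] - 1; // R side is 1-based
        if (rb.p < 0 || rb.p >= L - 1) stop("p_site outside the open reading frame");
        rb.a_trna = CharacterVector::is_na(at[r]) ? -1 : trna_index(S, std::string(at[r]));
        rb.p_trna = CharacterVector::is_na(pt[r]) ? -1 : trna_index(S, std::string(pt[r]));
        rb.rf = rf[r];
        rb.t_init = 0; rb.t_eb = 0; rb.t_ee = 0; rb.t_wait = 0;
        rb.dwell_stalled = false; rb.stall_pending = false;
        ribs.push_back(rb);
      }
      std::sort(ribs.begin(), ribs.end(),
                [](const Rib& a, const Rib& b) { return a.p > b.p; });
      for (size_t r = 1; r < ribs.size(); ++r)
        if (ribs[r - 1].p == ribs[r].p)
          stop("two ribosomes share one P site");
      st.mrnas[i].ribs = ribs;
    }
  }
  st.dec_count.assign(64, 0.0);
  st.dec_wait.assign(64, 0.0);
  st.dec_stall.assign(64, 0.0);
  st.evt.assign((size_t)(S.N + 1) * N_REAC, 0.0);
  return st;
}

static DataFrame reactions_to_df(const System& S, const State& st,
                                 const std::vector<Reaction>& rx) {
  int n = rx.size();
  CharacterVector name(n), trna(n);
  IntegerVector mrna(n), p_site(n);
  NumericVector prop(n);
  for (int q = 0; q < n; ++q) {
    name[q] = REAC_NAMES[rx[q].type];
    mrna[q] = rx[q].mrna + 1; // 0 => global
    if (rx[q].mrna >= 0 && rx[q].rib >= 0)
      p_site[q] = st.mrnas[rx[q].mrna].ribs[rx[q].rib].p + 1;
    else p_site[q] = NA_INTEGER;
    if (rx[q].trna >= 0) trna[q] = S.trna_names[rx[q].trna];
    else trna[q] = NA_STRING;
    prop[q] = rx[q].prop;
  }
  return DataFrame::create(_["reaction"] = name, _["mrna"] = mrna,
                           _["p_site"] = p_site, _["trna"] = trna,
                           _["propensity"] = prop,
                           _["stringsAsFactors"] = false);
}

static List dump_state(const System& S, const State& st) {
  NumericVector pv(N_POOL);
  CharacterVector pn(N_POOL);
  for (int p = 0; p < N_POOL; ++p) { pv[p] = (double)st.pools[p]; pn[p] = POOL_NAMES[p]; }
  pv.names() = pn;
  NumericVector da(S.n_trna), ch(S.n_trna), ft(S.n_trna);
  CharacterVector tn(S.n_trna);
  for (int t = 0; t < S.n_trna; ++t) {
    da[t] = (double)st.deacyl[t]; ch[t] = (double)st.charged[t]; ft[t] = (double)st.ftc[t];
    tn[t] = S.trna_names[t];
  }
  da.names() = tn; ch.names() = clone(tn); ft.names() = clone(tn);
  List rl(S.N);
  for (int i = 0; i < S.N; ++i) {
    const MRna& m = st.mrnas[i];
    int n = m.ribs.size();
    CharacterVector ph(n), at(n), pt(n);
    IntegerVector ps(n), rf(n);
    // dump in ascending P-site order (5' to 3')
    for (int q = 0; q < n; ++q) {
      const Rib& rb = m.ribs[n - 1 - q];
      ph[q] = PHASE_NAMES[rb.phase];
      ps[q] = rb.p + 1;
      if (rb.a_trna >= 0) at[q] = S.trna_names[rb.a_trna];
      else if (rb.a_trna == -2) at[q] = "initiator";
      else at[q] = NA_STRING;
      if (rb.p_trna >= 0) pt[q] = S.trna_names[rb.p_trna];
      else if (rb.p_trna == -2) pt[q] = "initiator";
      else pt[q] = NA_STRING;
      rf[q] = rb.rf;
    }
    rl[i] = DataFrame::create(_["phase"] = ph, _["p_site"] = ps,
                              _["a_trna"] = at, _["p_trna"] = pt, _["rf"] = rf,
                              _["stringsAsFactors"] = false);
  }
  return List::create(_["pools"] = pv, _["deacylated"] = da, _["charged"] = ch,
                      _["free_tc"] = ft, _["ribosomes"] = rl);
}

static List totals_list(const System& S, const State& st) {
  std::vector<double> tf, tt;
  totals_scan(S, st, tf, tt);
  NumericVector fx(tf.begin(), tf.end());
  fx.names() = CharacterVector::create("total_30S", "total_50S", "EfTu", "EfTs",
                                       "EfG", "RF1", "RF2", "RF3", "RRF", "mRNAs");
  NumericVector tr(tt.begin(), tt.end());
  CharacterVector tn(S.n_trna);
  for (int t = 0; t < S.n_trna; ++t) tn[t] = S.trna_names[t];
  tr.names() = tn;
  return List::create(_["factors"] = fx, _["trna"] = tr);
}

// ===========================================================================
// Exported: reaction inspection + single-reaction firing (for unit tests and
// interactive exploration of the catalogue)
// ===========================================================================

// [[Rcpp::export]]
DataFrame cpp_enumerate(List sys, List state) {
  System S = parse_system(sys);
  State st = parse_state(S, state);
  std::vector<Reaction> rx;
  for (int i = 0; i < S.N; ++i) enumerate_local(S, st, i, rx);
  enumerate_global(S, st, rx);
  return reactions_to_df(S, st, rx);
}

// [[Rcpp::export]]
List cpp_fire(List sys, List state, std::string reaction, int mrna,
              int p_site, std::string trna) {
  System S = parse_system(sys);
  State st = parse_state(S, state);
  st.keep_log = true; st.log_cap = 1000;
  std::vector<Reaction> rx;
  for (int i = 0; i < S.N; ++i) enumerate_local(S, st, i, rx);
  enumerate_global(S, st, rx);
  int want = -1;
  for (int q = 0; q < N_REAC; ++q)
    if (reaction == REAC_NAMES[q]) { want = q; break; }
  if (want < 0) stop("unknown reaction name '%s'", reaction.c_str());
  int tw = (trna == "") ? -1 : trna_index(S, trna);
  for (size_t q = 0; q < rx.size(); ++q) {
    const Reaction& r = rx[q];
    if (r.type != want) continue;
    if (r.mrna + 1 != mrna) continue;
    if (p_site != NA_INTEGER && r.mrna >= 0 && r.rib >= 0 &&
        st.mrnas[r.mrna].ribs[r.rib].p + 1 != p_site) continue;
    if (tw >= 0 && r.trna != tw) continue;
    std::vector<Delta> deltas;
    apply_reaction(S, st, r, deltas);
    List out = dump_state(S, st);
    out["totals"] = totals_list(S, st);
    if (!st.log_codon.empty()) {
      out["decode_codon"] = st.log_codon[0];
      out["decode_trna"] = S.trna_names[st.log_trna[0]];
    }
    out["completions"] = (int)st.cmp_gene.size();
    return out;
  }
  stop("reaction '%s' is not currently fireable at the requested locus",
       reaction.c_str());
}

// [[Rcpp::export]]
List cpp_state_totals(List sys, List state) {
  System S = parse_system(sys);
  State st = parse_state(S, state);
  return totals_list(S, st);
}

// ===========================================================================
// Exported: propensity tree primitives
// ===========================================================================

// [[Rcpp::export]]
List cpp_tree_build(NumericVector phis) {
  int L = phis.size();
  if (L < 1) stop("cannot build a propensity tree with no leaves");
  for (int i = 0; i < L; ++i)
    if (phis[i] < 0) stop("negative propensity at leaf %d", i + 1);
  Tree tr; tr.init(L);
  // bottom-up fill
  for (int i = 0; i < L; ++i) tr.node[tr.P + i] = phis[i];
  for (int v = tr.P - 1; v >= 1; --v) tr.node[v] = tr.node[2 * v] + tr.node[2 * v + 1];
  return List::create(_["nodes"] = NumericVector(tr.node.begin(), tr.node.end()),
                      _["n_leaves"] = L, _["padded"] = tr.P);
}

// [[Rcpp::export]]
List cpp_tree_update(List tree, int leaf, double phi) {
  if (phi < 0) stop("negative propensity");
  Tree tr;
  NumericVector nd = tree["nodes"];
  tr.L = tree["n_leaves"]; tr.P = tree["padded"];
  tr.node = std::vector<double>(nd.begin(), nd.end());
  if (leaf < 1 || leaf > tr.L) stop("leaf index out of range");
  int touched = tr.set(leaf - 1, phi);
  return List::create(_["nodes"] = NumericVector(tr.node.begin(), tr.node.end()),
                      _["n_leaves"] = tr.L, _["padded"] = tr.P,
                      _["touched"] = touched);
}

// [[Rcpp::export]]
int cpp_tree_select(List tree, double r) {
  Tree tr;
  NumericVector nd = tree["nodes"];
  tr.L = tree["n_leaves"]; tr.P = tree["padded"];
  tr.node = std::vector<double>(nd.begin(), nd.end());
  if (tr.root() <= 0) stop("total propensity is zero: nothing to select");
  if (r < 0 || r >= 1) stop("r must lie in [0, 1)");
  return tr.select(r) + 1;
}

// [[Rcpp::export]]
NumericVector cpp_draw_dt(int n, double phi, int seed) {
  if (phi <= 0) stop("total propensity must be positive");
  Rng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rexp(phi);
  return out;
}

// ===========================================================================
// Exported: full simulation
// ===========================================================================

static List collect_results(const System& S, const State& st, const Observer& ob,
                            long events, std::string status,
                            CharacterVector starved, double max_phi_dev,
                            double min_sep_seen) {
  // completions
  int nc = st.cmp_gene.size();
  CharacterVector gene(nc);
  IntegerVector len(nc);
  NumericVector ti(nc), teb(nc), tee(nc), trl(nc);
  for (int q = 0; q < nc; ++q) {
    gene[q] = S.gene_names[st.cmp_gene[q]];
    len[q] = st.cmp_len[q];
    ti[q] = st.cmp_tinit[q]; teb[q] = st.cmp_teb[q];
    tee[q] = st.cmp_tee[q];  trl[q] = st.cmp_trel[q];
  }
  DataFrame completions = DataFrame::create(
    _["gene"] = gene, _["length_aa"] = len, _["t_init"] = ti,
    _["t_elong_begin"] = teb, _["t_elong_end"] = tee, _["t_release"] = trl,
    _["stringsAsFactors"] = false);

  // codon decode stats
  CharacterVector codn(64);
  static const char* B = "ACGU";
  for (int c = 0; c < 64; ++c) {
    char buf[4] = { B[c / 16], B[(c / 4) % 4], B[c % 4], 0 };
    codn[c] = buf;
  }
  DataFrame codon_stats = DataFrame::create(
    _["codon"] = codn,
    _["n_events"] = NumericVector(st.dec_count.begin(), st.dec_count.end()),
    _["total_wait"] = NumericVector(st.dec_wait.begin(), st.dec_wait.end()),
    _["n_stalled"] = NumericVector(st.dec_stall.begin(), st.dec_stall.end()),
    _["stringsAsFactors"] = false);

  // checkpoints
  int nk = ob.t.size();
  DataFrame checkpoints = DataFrame::create(
    _["time"] = NumericVector(ob.t.begin(), ob.t.end()),
    _["free_50S"] = IntegerVector(ob.n_free50.begin(), ob.n_free50.end()),
    _["free_30S_PIC"] = IntegerVector(ob.n_free30.begin(), ob.n_free30.end()),
    _["initiating"] = IntegerVector(ob.n_init.begin(), ob.n_init.end()),
    _["elongating"] = IntegerVector(ob.n_elong.begin(), ob.n_elong.end()),
    _["terminating"] = IntegerVector(ob.n_term.begin(), ob.n_term.end()),
    _["stalled"] = IntegerVector(ob.n_stalled.begin(), ob.n_stalled.end()),
    _["bound"] = IntegerVector(ob.n_bound.begin(), ob.n_bound.end()));

  NumericMatrix ftc_m(nk, S.n_trna), pool_m(nk, N_POOL),
                totf_m(nk, 10), tott_m(nk, S.n_trna);
  for (int r = 0; r < nk; ++r) {
    for (int t = 0; t < S.n_trna; ++t) {
      ftc_m(r, t) = ob.ftc_rows[r][t];
      tott_m(r, t) = ob.tot_trna_rows[r][t];
    }
    for (int p = 0; p < N_POOL; ++p) pool_m(r, p) = ob.pool_rows[r][p];
    for (int p = 0; p < 10; ++p) totf_m(r, p) = ob.tot_fixed_rows[r][p];
  }
  CharacterVector tn(S.n_trna);
  for (int t = 0; t < S.n_trna; ++t) tn[t] = S.trna_names[t];
  colnames(ftc_m) = tn; colnames(tott_m) = clone(tn);
  CharacterVector pnm(N_POOL);
  for (int p = 0; p < N_POOL; ++p) pnm[p] = POOL_NAMES[p];
  colnames(pool_m) = pnm;
  colnames(totf_m) = CharacterVector::create(
    "total_30S", "total_50S", "EfTu", "EfTs", "EfG", "RF1", "RF2", "RF3",
    "RRF", "mRNAs");

  List out = List::create(
    _["completions"] = completions,
    _["codon_stats"] = codon_stats,
    _["checkpoints"] = checkpoints,
    _["free_tc"] = ftc_m,
    _["pool_series"] = pool_m,
    _["totals_factors"] = totf_m,
    _["totals_trna"] = tott_m,
    _["final_state"] = dump_state(S, st),
    _["final_totals"] = totals_list(S, st),
    _["t_final"] = st.t,
    _["n_events"] = (double)events,
    _["status"] = status,
    _["starved"] = starved,
    _["max_phi_rel_dev"] = max_phi_dev,
    _["min_p_site_separation"] = min_sep_seen,
    _["dt_sum"] = st.dt_sum,
    _["dt_sumsq"] = st.dt_sumsq);
  {
    NumericMatrix em(S.N + 1, N_REAC);
    for (int i = 0; i <= S.N; ++i)
      for (int q = 0; q < N_REAC; ++q)
        em(i, q) = st.evt[(size_t)i * N_REAC + q];
    CharacterVector rn(N_REAC);
    for (int q = 0; q < N_REAC; ++q) rn[q] = REAC_NAMES[q];
    colnames(em) = rn;
    out["event_counts"] = em;
  }
  if (st.keep_log) {
    int nl = st.log_codon.size();
    CharacterVector lc(nl), lt(nl);
    for (int q = 0; q < nl; ++q) {
      int c = st.log_codon[q];
      char buf[4] = { B[c / 16], B[(c / 4) % 4], B[c % 4], 0 };
      lc[q] = buf;
      lt[q] = S.trna_names[st.log_trna[q]];
    }
    out["decode_log"] = DataFrame::create(
      _["time"] = NumericVector(st.log_t.begin(), st.log_t.end()),
      _["codon"] = lc, _["trna"] = lt,
      _["wait"] = NumericVector(st.log_wait.begin(), st.log_wait.end()),
      _["stalled"] = LogicalVector(st.log_stall.begin(), st.log_stall.end()),
      _["stringsAsFactors"] = false);
  }
  return out;
}

static CharacterVector starved_channels(const System& S, const State& st) {
  std::vector<std::string> out;
  std::vector<bool> waiting(N_CHAN_FIXED + S.n_trna, false);
  for (int i = 0; i < S.N; ++i) {
    const MRna& m = st.mrnas[i];
    const std::vector<int>& cod = S.gene_codons[m.gene];
    for (size_t j = 0; j < m.ribs.size(); ++j) {
      const Rib& rb = m.ribs[j];
      switch (rb.phase) {
      case PH_INIT30S: waiting[CH_50S] = true; break;
      case PH_WAIT_TC: {
        const std::vector<int>& ts = S.codon_trnas[cod[rb.p + 1]];
        for (size_t q = 0; q < ts.size(); ++q) waiting[N_CHAN_FIXED + ts[q]] = true;
        break;
      }
      case PH_PRETRL: waiting[CH_EFG] = true; break;
      case PH_TWRF: {
        int c = cod[rb.p + 1];
        if (c == COD_UAA || c == COD_UAG) waiting[CH_RF1] = true;
        if (c == COD_UAA || c == COD_UGA) waiting[CH_RF2] = true;
        break;
      }
      case PH_TREL: waiting[CH_RF3] = true; break;
      case PH_TPOST: waiting[CH_RRF] = true; break;
      default: break;
      }
    }
  }
  const char* fixed_nm[N_CHAN_FIXED] = {
    "free_30S_PIC", "free_50S", "EfG_GTP", "RF1", "RF2", "RF3_GTP", "RRF" };
  long pools_for[N_CHAN_FIXED] = {
    st.pools[P30S], st.pools[P50S], st.pools[G_GTP], st.pools[PRF1],
    st.pools[PRF2], st.pools[RF3_GTP], st.pools[PRRF] };
  for (int c = 0; c < N_CHAN_FIXED; ++c)
    if (waiting[c] && pools_for[c] == 0) out.push_back(fixed_nm[c]);
  for (int t = 0; t < S.n_trna; ++t)
    if (waiting[N_CHAN_FIXED + t] && st.ftc[t] == 0)
      out.push_back("free_TC:" + S.trna_names[t]);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_simulate(List sys, List state, List options) {
  System S = parse_system(sys);
  State st = parse_state(S, state);

  double t_end = as<double>(options["t_end"]);
  uint64_t seed = (uint64_t)as<double>(options["seed"]);
  double sample_every = as<double>(options["sample_every"]);
  std::string engine = as<std::string>(options["engine"]);
  double max_events = as<double>(options["max_events"]);
  long check_every = (long)as<double>(options["check_every"]);
  long resync_every = (long)as<double>(options["resync_every"]);
  st.keep_log = as<bool>(options["keep_decode_log"]);
  st.log_cap = (size_t)as<double>(options["decode_log_max"]);
  bool track_min_sep = as<bool>(options["track_min_separation"]);

  Rng rng(seed);
  Observer ob;
  ob.record(S, st); // t = 0 snapshot
  double next_sample = sample_every > 0 ? sample_every : R_PosInf;

  long events = 0;
  std::string status = "completed";
  CharacterVector starved;
  double max_phi_dev = 0.0;
  double min_sep = R_PosInf;

  if (engine == "tree") {
    Book bk;
    bk.init(S, st);
    while (true) {
      if ((events & 0x3FF) == 0) Rcpp::checkUserInterrupt();
      double Phi = bk.tree.root();
      if (Phi <= 1e-300) {
        status = "deadlock";
        starved = starved_channels(S, st);
        break;
      }
      double dt = rng.rexp(Phi);
      double t_next = st.t + dt;
      while (next_sample <= t_next && next_sample <= t_end + 1e-12) {
        double keep = st.t; st.t = next_sample;
        ob.record(S, st); st.t = keep;
        next_sample += sample_every;
      }
      if (t_next >= t_end) { st.t = t_end; break; }
      st.t = t_next;
      st.dt_sum += dt; st.dt_sumsq += dt * dt;
      int leaf = bk.tree.select(rng.unif());
      std::vector<Delta> deltas;
      if (leaf == S.N) { // global reactions leaf
        std::vector<Reaction> rx;
        enumerate_global(S, st, rx);
        double sum = 0.0;
        for (size_t q = 0; q < rx.size(); ++q) sum += rx[q].prop;
        if (sum <= 0) { // tiny numerical residue on the leaf; resync
          bk.recompute_global(S, st);
          continue;
        }
        double x = rng.unif() * sum;
        size_t pick = 0;
        for (; pick + 1 < rx.size(); ++pick) {
          if (x < rx[pick].prop) break;
          x -= rx[pick].prop;
        }
        apply_reaction(S, st, rx[pick], deltas);
        st.evt[(size_t)S.N * N_REAC + rx[pick].type] += 1;
        for (size_t q = 0; q < deltas.size(); ++q)
          bk.pool_delta(S, st, deltas[q], -1);
        bk.recompute_global(S, st);
      } else {
        std::vector<Reaction> rx;
        enumerate_local(S, st, leaf, rx);
        double sum = 0.0;
        for (size_t q = 0; q < rx.size(); ++q) sum += rx[q].prop;
        if (sum <= 0) {
          bk.recompute_mrna(S, st, leaf);
          continue;
        }
        double x = rng.unif() * sum;
        size_t pick = 0;
        for (; pick + 1 < rx.size(); ++pick) {
          if (x < rx[pick].prop) break;
          x -= rx[pick].prop;
        }
        apply_reaction(S, st, rx[pick], deltas);
        st.evt[(size_t)leaf * N_REAC + rx[pick].type] += 1;
        for (size_t q = 0; q < deltas.size(); ++q)
          bk.pool_delta(S, st, deltas[q], leaf);
        bk.recompute_mrna(S, st, leaf);
        bk.recompute_global(S, st);
        if (track_min_sep) {
          const MRna& m = st.mrnas[leaf];
          for (size_t j = 1; j < m.ribs.size(); ++j) {
            double sep = m.ribs[j - 1].p - m.ribs[j].p;
            if (sep < min_sep) min_sep = sep;
          }
        }
      }
      ++events;
      if (check_every > 0 && events % check_every == 0) {
        // spot-check: maintained root vs full recomputation
        double maintained = bk.tree.root();
        Book fresh;
        fresh.init(S, st);
        double truth = fresh.tree.root();
        double dev = std::fabs(maintained - truth) /
                     std::max(1.0, std::fabs(truth));
        if (dev > max_phi_dev) max_phi_dev = dev;
        if (dev > 1e-6)
          stop("propensity bookkeeping drifted (rel dev %g) after %ld events",
               dev, events);
      }
      if (resync_every > 0 && events % resync_every == 0) bk.init(S, st);
      if (events >= (long)max_events) { status = "max_events"; break; }
    }
  } else if (engine == "naive") {
    while (true) {
      if ((events & 0xFF) == 0) Rcpp::checkUserInterrupt();
      std::vector<Reaction> rx;
      for (int i = 0; i < S.N; ++i) enumerate_local(S, st, i, rx);
      enumerate_global(S, st, rx);
      double Phi = 0.0;
      for (size_t q = 0; q < rx.size(); ++q) Phi += rx[q].prop;
      if (Phi <= 0) {
        status = "deadlock";
        starved = starved_channels(S, st);
        break;
      }
      double dt = rng.rexp(Phi);
      double t_next = st.t + dt;
      while (next_sample <= t_next && next_sample <= t_end + 1e-12) {
        double keep = st.t; st.t = next_sample;
        ob.record(S, st); st.t = keep;
        next_sample += sample_every;
      }
      if (t_next >= t_end) { st.t = t_end; break; }
      st.t = t_next;
      st.dt_sum += dt; st.dt_sumsq += dt * dt;
      double x = rng.unif() * Phi;
      size_t pick = 0;
      for (; pick + 1 < rx.size(); ++pick) {
        if (x < rx[pick].prop) break;
        x -= rx[pick].prop;
      }
      std::vector<Delta> deltas;
      apply_reaction(S, st, rx[pick], deltas);
      st.evt[(size_t)(rx[pick].mrna < 0 ? S.N : rx[pick].mrna) * N_REAC +
             rx[pick].type] += 1;
      if (track_min_sep && rx[pick].mrna >= 0) {
        const MRna& m = st.mrnas[rx[pick].mrna];
        for (size_t j = 1; j < m.ribs.size(); ++j) {
          double sep = m.ribs[j - 1].p - m.ribs[j].p;
          if (sep < min_sep) min_sep = sep;
        }
      }
      ++events;
      if (events >= (long)max_events) { status = "max_events"; break; }
    }
  } else {
    stop("unknown engine '%s' (use \"tree\" or \"naive\")", engine.c_str());
  }

  // final checkpoint at t_final
  ob.record(S, st);
  return collect_results(S, st, ob, events, status, starved, max_phi_dev,
                         min_sep);
}
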