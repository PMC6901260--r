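// Monte-Carlo core for polymerase dynamics on a tandem reporter array.
// Fixed-step Bernoulli scheme: each rate r fires in a step with probability
// r*dt (dt guarded in R so r*dt <= 0.1). All randomness comes from a
// self-contained splitmix64 stream so runs are bit-reproducible from an
// integer seed, independent of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  // uniform in [0, 1) with 53-bit resolution
  double unif() { return (splitmix64_next(s) >> 11) * (1.0 / 9007199254740992.0); }
};

struct Gene {
  double length, ms2_start, ms2_end, exon_probe_end, footprint;
  int n_copies;
  std::vector<double> intron_end;  // 3' ends, sorted
  std::vector<int> probe;          // 1 if intron carries the probe
};

struct Par {
  double init, v, pon, poff, term, ret_mean, depl, dt;
  bool ret_fixed;
};

struct Pol {
  double pos;
  bool paused, at_end;
  double bleached;  // MS2 fraction synthesized before the last bleach
};

// Completed transcripts awaiting release. ms2 signal of a completed
// transcript is always 1 (the MS2 region lies within the gene), its intron
// mask and exon flag are fixed functions of the gene end, so only the
// release deadline and the bleached fraction need to be carried.
struct Ret {
  double deadline, bleached;
};
struct MinDeadline {
  bool operator()(const Ret &a, const Ret &b) const { return a.deadline > b.deadline; }
};

struct Site {
  double clock;
  Rng rng;
  std::vector<std::vector<Pol>> copies;
  std::vector<Ret> retained;  // min-heap on deadline
};

static Gene parse_gene(const List &g) {
  Gene G;
  G.length = as<double>(g["length_bp"]);
  NumericVector ms2 = g["ms2_region"];
  G.ms2_start = ms2[0];
  G.ms2_end = ms2[1];
  NumericVector ep = g["exon_probe"];
  G.exon_probe_end = ep[1];
  G.n_copies = as<int>(g["n_copies"]);
  G.footprint = as<double>(g["footprint_bp"]);
  NumericMatrix intr = g["introns"];
  IntegerVector probe_idx = g["intron_probe_indices"];
  std::vector<bool> has(intr.nrow(), false);
  for (int i = 0; i < probe_idx.size(); ++i) has[probe_idx[i] - 1] = true;
  for (int i = 0; i < intr.nrow(); ++i) {
    G.intron_end.push_back(intr(i, 1));
    G.probe.push_back(has[i] ? 1 : 0);
  }
  return G;
}

static Par parse_par(const List &p) {
  Par P;
  P.init = as<double>(p["init_rate"]);
  P.v = as<double>(p["elong_rate"]);
  P.pon = as<double>(p["pause_on_rate"]);
  P.poff = as<double>(p["pause_off_rate"]);
  P.term = as<double>(p["termination_rate"]);
  P.ret_mean = as<double>(p["retention_mean"]);
  P.depl = as<double>(p["splice_depletion_bp"]);
  P.dt = as<double>(p["dt"]);
  P.ret_fixed = as<std::string>(p["retention_model"]) == "fixed";
  return P;
}

static inline double ms2_frac(double pos, const Gene &G) {
  double f = (pos - G.ms2_start) / (G.ms2_end - G.ms2_start);
  if (f < 0) f = 0;
  if (f > 1) f = 1;
  return f;
}

// number of probe-carrying introns still present on a transcript whose
// polymerase sits at `pos` (signal appears at the intron 3' end and is
// depleted `depl` bp further downstream)
static inline int probe_introns_at(double pos, const Gene &G, const Par &P) {
  int n = 0;
  for (size_t i = 0; i < G.intron_end.size(); ++i)
    if (G.probe[i] && pos >= G.intron_end[i] && pos < G.intron_end[i] + P.depl) ++n;
  return n;
}

static void do_step(Site &S, const Gene &G, const Par &P) {
  const double adv = P.v * P.dt;
  for (int c = 0; c < G.n_copies; ++c) {
    std::vector<Pol> &pols = S.copies[c];
    double ahead = std::numeric_limits<double>::infinity();
    bool released = false;
    for (size_t i = 0; i < pols.size(); ++i) {
      Pol &p = pols[i];
      if (p.at_end) {
        // release attempt; only the front polymerase can be at the gene end
        if (S.rng.unif() < P.term * P.dt) {
          double d = P.ret_mean;
          if (!P.ret_fixed)
            d = (P.ret_mean > 0) ? -P.ret_mean * std::log(1.0 - S.rng.unif()) : 0.0;
          Ret r;
          r.deadline = S.clock + P.dt + d;
          r.bleached = p.bleached;
          S.retained.push_back(r);
          std::push_heap(S.retained.begin(), S.retained.end(), MinDeadline());
          p.pos = -1.0;  // mark for removal
          released = true;
        } else {
          ahead = G.length;
        }
        continue;
      }
      if (p.paused) {
        if (S.rng.unif() < P.poff * P.dt) p.paused = false;
      } else if (P.pon > 0) {
        if (S.rng.unif() < P.pon * P.dt) p.paused = true;
      }
      if (!p.paused) {
        double np = p.pos + adv;
        if (np > ahead - G.footprint) np = ahead - G.footprint;
        if (np < p.pos) np = p.pos;
        if (np >= G.length) {
          np = G.length;
          p.at_end = true;
        }
        p.pos = np;
      }
      ahead = p.pos;
    }
    if (released)
      pols.erase(std::remove_if(pols.begin(), pols.end(),
                                [](const Pol &q) { return q.pos < 0; }),
                 pols.end());
    // initiation, gated on a clear promoter-proximal footprint
    bool clear = pols.empty() || pols.back().pos >= G.footprint;
    double u = S.rng.unif();
    if (clear && u < P.init * P.dt) {
      Pol np;
      np.pos = 0.0;
      np.paused = false;
      np.at_end = false;
      np.bleached = 0.0;
      pols.push_back(np);
    }
  }
  S.clock += P.dt;
  while (!S.retained.empty() && S.retained.front().deadline <= S.clock) {
    std::pop_heap(S.retained.begin(), S.retained.end(), MinDeadline());
    S.retained.pop_back();
  }
}

// channel totals: unbleached MS2, bleached MS2, intron-probe count,
// exon-probe count, transcript count
static void record(const Site &S, const Gene &G, const Par &P, double *out) {
  double unb = 0, bl = 0, intr = 0, ex = 0, cnt = 0;
  for (int c = 0; c < G.n_copies; ++c) {
    for (const Pol &p : S.copies[c]) {
      double f = ms2_frac(p.pos, G);
      unb += f - p.bleached;
      bl += p.bleached;
      intr += probe_introns_at(p.pos, G, P);
      if (p.pos >= G.exon_probe_end) ex += 1;
      cnt += 1;
    }
  }
  int end_probe = probe_introns_at(G.length, G, P);
  for (const Ret &r : S.retained) {
    unb += 1.0 - r.bleached;
    bl += r.bleached;
    cnt += 1;
  }
  intr += (double)S.retained.size() * end_probe;
  ex += (double)S.retained.size();
  out[0] = unb;
  out[1] = bl;
  out[2] = intr;
  out[3] = ex;
  out[4] = cnt;
}

static void bleach_site(Site &S, const Gene &G) {
  for (auto &pols : S.copies)
    for (Pol &p : pols) p.bleached = ms2_frac(p.pos, G);
  for (Ret &r : S.retained) r.bleached = 1.0;
}

// ---- SiteState marshalling (R list <-> Site) ----

static Site state_from_r(const List &st, const Gene &G) {
  Site S;
  S.clock = as<double>(st["clock"]);
  NumericVector rng = st["rng_state"];
  S.rng.s = ((uint64_t)(double)rng[0] << 32) | (uint64_t)(double)rng[1];
  S.copies.assign(G.n_copies, std::vector<Pol>());
  NumericMatrix pm = st["pols"];
  for (int i = 0; i < pm.nrow(); ++i) {
    Pol p;
    int c = (int)pm(i, 0) - 1;
    p.pos = pm(i, 1);
    p.paused = pm(i, 2) != 0;
    p.at_end = pm(i, 3) != 0;
    p.bleached = pm(i, 4);
    S.copies[c].push_back(p);
  }
  NumericMatrix rm = st["retained"];
  for (int i = 0; i < rm.nrow(); ++i) {
    Ret r;
    r.deadline = rm(i, 0);
    r.bleached = rm(i, 1);
    S.retained.push_back(r);
  }
  std::make_heap(S.retained.begin(), S.retained.end(), MinDeadline());
  return S;
}

static List state_to_r(const Site &S) {
  int np = 0;
  for (const auto &pols : S.copies) np += (int)pols.size();
  NumericMatrix pm(np, 5);
  colnames(pm) = CharacterVector::create("copy", "position", "paused", "at_end", "bleached");
  int row = 0;
  for (size_t c = 0; c < S.copies.size(); ++c) {
    for (const Pol &p : S.copies[c]) {
      pm(row, 0) = (double)(c + 1);
      pm(row, 1) = p.pos;
      pm(row, 2) = p.paused ? 1.0 : 0.0;
      pm(row, 3) = p.at_end ? 1.0 : 0.0;
      pm(row, 4) = p.bleached;
      ++row;
    }
  }
  // dump the heap in deadline order so the marshalled form is canonical
  std::vector<Ret> ret = S.retained;
  std::sort(ret.begin(), ret.end(),
            [](const Ret &a, const Ret &b) { return a.deadline < b.deadline; });
  NumericMatrix rm((int)ret.size(), 2);
  colnames(rm) = CharacterVector::create("release_deadline", "bleached");
  for (size_t i = 0; i < ret.size(); ++i) {
    rm((int)i, 0) = ret[i].deadline;
    rm((int)i, 1) = ret[i].bleached;
  }
  NumericVector rng(2);
  rng[0] = (double)(S.rng.s >> 32);
  rng[1] = (double)(S.rng.s & 0xFFFFFFFFULL);
  return List::create(_["clock"] = S.clock, _["pols"] = pm, _["retained"] = rm,
                      _["rng_state"] = rng);
}

static uint64_t site_seed(double seed, int site) {
  uint64_t s = (uint64_t)(int64_t)seed;
  s ^= 0xD1B54A32D192ED03ULL * (uint64_t)(site + 1);
  splitmix64_next(s);  // scramble
  return s;
}

// ---- exported entry points ----

// [[Rcpp::export]]
List sim_advance_cpp(List gene, List params, List state, int n_steps, int record_every) {
  Gene G = parse_gene(gene);
  Par P = parse_par(params);
  Site S = state_from_r(state, G);
  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix rec(n_rec, 6);
  if (n_rec > 0)
    colnames(rec) = CharacterVector::create("time_s", "total_ms2", "total_bleached",
                                            "intron_signal", "exon_signal", "n_transcripts");
  double buf[5];
  int row = 0;
  for (int k = 1; k <= n_steps; ++k) {
    do_step(S, G, P);
    if (record_every > 0 && k % record_every == 0 && row < n_rec) {
      record(S, G, P, buf);
      rec(row, 0) = S.clock;
      for (int j = 0; j < 5; ++j) rec(row, j + 1) = buf[j];
      ++row;
    }
  }
  return List::create(_["state"] = state_to_r(S), _["record"] = rec);
}

// [[Rcpp::export]]
NumericVector sim_record_cpp(List gene, List params, List state) {
  Gene G = parse_gene(gene);
  Par P = parse_par(params);
  Site S = state_from_r(state, G);
  NumericVector out(5);
  double buf[5];
  record(S, G, P, buf);
  for (int j = 0; j < 5; ++j) out[j] = buf[j];
  out.names() = CharacterVector::create("total_ms2", "total_bleached", "intron_signal",
                                        "exon_signal", "n_transcripts");
  return out;
}

// Per-site FRAP: burn in for `burnin` seconds, bleach, then sample the
// unbleached and bleached MS2 totals at `frame_times` (seconds relative to
// the bleach; negative = pre-bleach). Frame times snap to the step grid.
// [[Rcpp::export]]
List sim_frap_cpp(List gene, List params, double burnin, NumericVector frame_times,
                  int n_sites, double seed) {
  Gene G = parse_gene(gene);
  Par P = parse_par(params);
  int nf = frame_times.size();
  std::vector<long> frame_step(nf);
  long bleach_step = (long)std::llround(burnin / P.dt);
  long last_step = bleach_step;
  for (int j = 0; j < nf; ++j) {
    frame_step[j] = (long)std::llround((burnin + frame_times[j]) / P.dt);
    if (frame_step[j] < 0) frame_step[j] = 0;
    if (frame_step[j] > last_step) last_step = frame_step[j];
  }
  NumericMatrix unb(n_sites, nf), bl(n_sites, nf);
  double buf[5];
  for (int i = 0; i < n_sites; ++i) {
    Site S;
    S.clock = 0.0;
    S.rng.s = site_seed(seed, i);
    S.copies.assign(G.n_copies, std::vector<Pol>());
    int j = 0;
    for (long k = 0; k <= last_step; ++k) {
      if (k > 0) do_step(S, G, P);
      if (k == bleach_step) bleach_site(S, G);
      while (j < nf && frame_step[j] == k) {
        record(S, G, P, buf);
        unb(i, j) = buf[0];
        bl(i, j) = buf[1];
        ++j;
      }
    }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["unbleached"] = unb, _["bleached"] = bl);
}

// Independent steady-state snapshots of the intron- and exon-probe channels.
// [[Rcpp::export]]
NumericMatrix sim_fish_cpp(List gene, List params, double burnin, int n_sites, double seed) {
  Gene G = parse_gene(gene);
  Par P = parse_par(params);
  long n_steps = (long)std::llround(burnin / P.dt);
  NumericMatrix out(n_sites, 2);
  colnames(out) = CharacterVector::create("intron_signal", "exon_signal");
  double buf[5];
  for (int i = 0; i < n_sites; ++i) {
    Site S;
    S.clock = 0.0;
    S.rng.s = site_seed(seed, i);
    S.copies.assign(G.n_copies, std::vector<Pol>());
    for (long k = 0; k < n_steps; ++k) do_step(S, G, P);
    record(S, G, P, buf);
    out(i, 0) = buf[2];
    out(i, 1) = buf[3];
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rng_state_from_seed_cpp(double seed) {
  uint64_t s = site_seed(seed, 0);
  NumericVector rng(2);
  rng[0] = (double)(s >> 32);
  rng[1] = (double)(s & 0xFFFFFFFFULL);
  return rng;
}
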