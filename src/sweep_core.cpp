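// Core simulation machinery: rescaled Wright-Fisher trajectories with
// selection, migration and drift in a two-deme out-of-Africa demography, and a
// discrete-generation structured coalescent (ancestral recombination graph
// with allelic classes) conditioned on a focal-allele frequency trajectory.
// All randomness goes through R's RNG so set.seed() governs every draw.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic Wright-Fisher selection update, genotype fitnesses 1 : 1+hs :
// 1+s acting on the derived allele at frequency p.
static inline double wf_update(double p, double s, double h) {
  if (s == 0.0 || p <= 0.0 || p >= 1.0) return p;
  double q = 1.0 - p;
  double wbar = p * p * (1.0 + s) + 2.0 * p * q * (1.0 + h * s) + q * q;
  return (p * p * (1.0 + s) + p * q * (1.0 + h * s)) / wbar;
}

// [[Rcpp::export]]
double cpp_wf_update(double p, double s, double h) { return wf_update(p, s, h); }

static inline int clampidx(int g, int len) { return g < len ? g : len - 1; }

static inline int rbinom_int(int n, double p) {
  if (n <= 0) return 0;
  if (p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int) R::rbinom((double) n, p);
}

// exact rescaling of a selection coefficient: one rescaled generation stands
// for lambda real generations, so the per-step growth factor is preserved
static inline double rescale_s(double s, double lambda) {
  return std::pow(1.0 + s, lambda) - 1.0;
}

// One forward pass from the mutation/onset generation to the present.
// Arrays are indexed by generations-before-present (rescaled units).
// K1/K2 are filled in place over [0, g_start]. Returns 1 if the final state
// segregates in both demes, 0 otherwise (with early exit on loss/fixation).
static int forward_pass(int model, int g_start, int k1_start, int k2_start,
                        double sA, double sNA, double h,
                        const IntegerVector& twoN1, const IntegerVector& twoN2,
                        const NumericVector& mig, int G_split,
                        std::vector<int>& K1, std::vector<int>& K2,
                        bool clear = true) {
  const int len = twoN1.size();
  if (clear) {
    K1.assign(g_start + 1, 0);
    K2.assign(g_start + 1, 0);
  }
  K1[g_start] = k1_start;
  K2[g_start] = k2_start;
  for (int g = g_start; g > 0; --g) {
    int gc = clampidx(g, len), gn = clampidx(g - 1, len);
    if (g - 1 >= G_split) {            // single (ancestral) deme
      double p = (double) K1[g] / twoN1[gc];
      double pp = wf_update(p, model == 1 ? sA : 0.0, h);
      K1[g - 1] = rbinom_int(twoN1[gn], pp);
      // loss is permanent; fixation cannot end segregating either
      if (K1[g - 1] == 0 || K1[g - 1] == twoN1[gn]) return 0;
    } else if (g >= G_split) {         // split: both demes inherit ancestral p
      double p = (double) K1[g] / twoN1[gc];
      double pp = wf_update(p, model == 1 ? sA : 0.0, h);
      K1[g - 1] = rbinom_int(twoN1[gn], pp);
      K2[g - 1] = rbinom_int(twoN2[gn], pp);
      if (K1[g - 1] == 0 && K2[g - 1] == 0) return 0;
    } else {                           // two demes: selection, migration, drift
      double p1 = (double) K1[g] / twoN1[gc];
      double p2 = (double) K2[g] / twoN2[gc];
      double p1s = wf_update(p1, model == 2 ? 0.0 : sA, h);
      double p2s = wf_update(p2, sNA, h);
      double m = mig[gc];
      K1[g - 1] = rbinom_int(twoN1[gn], (1.0 - m) * p1s + m * p2s);
      K2[g - 1] = rbinom_int(twoN2[gn], (1.0 - m) * p2s + m * p1s);
      bool lost = (K1[g - 1] == 0 && K2[g - 1] == 0);
      bool fixed = (K1[g - 1] == twoN1[gn] && K2[g - 1] == twoN2[gn]);
      if (lost || fixed) return 0;
    }
  }
  bool seg1 = K1[0] > 0 && K1[0] < twoN1[0];
  bool seg2 = K2[0] > 0 && K2[0] < twoN2[0];
  return (seg1 && seg2) ? 1 : 0;
}

// Trajectory of derived-allele copy counts conditioned on present-day
// segregation in both demes, for a FIXED scenario (the scenario is kept and
// the stochastic path rejection-resampled). model: 0 NTR, 1 SDN, 2 SSV.
// Selection coefficients and rates must already be in rescaled units.
// [[Rcpp::export]]
List cpp_wf_trajectory(int model, int g_mut, double f0,
                       double sA, double sNA, double h,
                       IntegerVector twoN1, IntegerVector twoN2,
                       NumericVector mig, int G_split,
                       int max_attempts, int backward_cap) {
  const int len = twoN1.size();
  std::vector<int> K1, K2;
  int attempts = 0;
  bool ok = false;
  int origin = g_mut;
  if (model == 2) {
    // the standing variant's onset state: frequency f0 in each deme at
    // t_mut (in the ancestral deme when t_mut predates the split); pastward
    // of the onset the allelic classes merge freely in the coalescent
    bool presplit = g_mut >= G_split;
    int k10 = std::max(1, (int) std::lround(twoN1[clampidx(g_mut, len)] * f0));
    int k20 = presplit ? 0
      : std::max(1, (int) std::lround(twoN2[clampidx(g_mut, len)] * f0));
    while (attempts < max_attempts) {
      ++attempts;
      if (forward_pass(2, g_mut, k10, k20, sA, sNA, h, twoN1, twoN2, mig,
                       G_split, K1, K2)) { ok = true; break; }
    }
  } else {
    // post-split onset: the new mutation enters each deme at one copy (the
    // per-deme onset-state convention); pre-split: one ancestral copy
    int k20 = (g_mut < G_split) ? 1 : 0;
    while (attempts < max_attempts) {
      ++attempts;
      if (forward_pass(model, g_mut, 1, k20, sA, sNA, h,
                       twoN1, twoN2, mig, G_split, K1, K2)) { ok = true; break; }
    }
  }
  if (!ok)
    return List::create(_["accepted"] = false, _["attempts"] = attempts);
  return List::create(_["accepted"] = true,
                      _["K1"] = IntegerVector(K1.begin(), K1.end()),
                      _["K2"] = IntegerVector(K2.begin(), K2.end()),
                      _["origin"] = origin,
                      _["attempts"] = attempts);
}

// Rejection sampling of (scenario, trajectory) jointly: the scenario is
// re-drawn from its uniform prior at every attempt, so the accepted draws
// follow the post-conditioning (non-uniform) effective prior. Ranges are in
// natural units (years, plain selection coefficients); rescaling by lambda
// happens here.
// [[Rcpp::export]]
List cpp_draw_conditioned(int model, double h,
                          NumericVector tmut_range, NumericVector sA_range,
                          NumericVector sNA_range, NumericVector f0_range,
                          double gen_years, double lambda,
                          IntegerVector twoN1, IntegerVector twoN2,
                          NumericVector mig, int G_split,
                          int max_draws, int backward_cap) {
  const int len = twoN1.size();
  std::vector<int> K1, K2;
  for (int a = 1; a <= max_draws; ++a) {
    double tmut = R::runif(tmut_range[0], tmut_range[1]);
    double sA = (model == 1) ? R::runif(sA_range[0], sA_range[1]) : 0.0;
    double sNA = (model == 0) ? 0.0 : R::runif(sNA_range[0], sNA_range[1]);
    double f0 = (model == 2) ? R::runif(f0_range[0], f0_range[1]) : NA_REAL;
    int g_mut = std::max(1, (int) std::lround(tmut / gen_years / lambda));
    int origin = g_mut;
    double sAr = rescale_s(sA, lambda), sNAr = rescale_s(sNA, lambda);
    if (model == 2) {
      bool presplit = g_mut >= G_split;
      int k10 = std::max(1, (int) std::lround(twoN1[clampidx(g_mut, len)] * f0));
      int k20 = presplit ? 0
        : std::max(1, (int) std::lround(twoN2[clampidx(g_mut, len)] * f0));
      if (!forward_pass(2, g_mut, k10, k20, 0.0, sNAr, h,
                        twoN1, twoN2, mig, G_split, K1, K2)) continue;
    } else {
      int k20 = (g_mut < G_split) ? 1 : 0;
      if (!forward_pass(model, g_mut, 1, k20, sAr, sNAr, h,
                        twoN1, twoN2, mig, G_split, K1, K2)) continue;
    }
    return List::create(_["accepted"] = true,
                        _["s_A"] = sA, _["s_NA"] = sNA, _["t_mut"] = tmut,
                        _["f0"] = f0, _["h"] = h,
                        _["K1"] = IntegerVector(K1.begin(), K1.end()),
                        _["K2"] = IntegerVector(K2.begin(), K2.end()),
                        _["origin"] = origin, _["attempts"] = a);
  }
  return List::create(_["accepted"] = false, _["attempts"] = max_draws);
}

// Unconditioned single-deme absorption run (for closed-form checks such as
// the neutral fixation probability 1/(2N)). Returns the final copy count.
// [[Rcpp::export]]
int cpp_wf_absorb(int twoN, double s, double h, int k0, int maxgen) {
  int k = k0;
  for (int g = 0; g < maxgen; ++g) {
    if (k == 0 || k == twoN) break;
    double pp = wf_update((double) k / twoN, s, h);
    k = rbinom_int(twoN, pp);
  }
  return k;
}

// ---------------------------------------------------------------------------
// Structured coalescent conditioned on the trajectory.

struct Bits {
  std::vector<uint64_t> w;
  explicit Bits(int words = 0) : w(words, 0ull) {}
  void set(int i) { w[i >> 6] |= (1ull << (i & 63)); }
  void orin(const Bits& o) { for (size_t i = 0; i < w.size(); ++i) w[i] |= o.w[i]; }
  bool operator==(const Bits& o) const { return w == o.w; }
  int count() const {
    int c = 0;
    for (uint64_t x : w) c += __builtin_popcountll(x);
    return c;
  }
};

struct Seg { double l, r; Bits d; };

struct Lin {
  int deme, cls;           // cls: 1 = derived (linked to focal), 0 = ancestral
  std::vector<Seg> segs;   // sorted, non-overlapping ancestral material
  bool alive;
};

static double mat_len(const Lin& x) {
  double s = 0.0;
  for (const Seg& sg : x.segs) s += sg.r - sg.l;
  return s;
}

// Merge the material of b into a (coalescence); drop intervals whose
// descendant set reaches all samples (local MRCA).
static void merge_lineages(Lin& a, Lin& b, int nsamp) {
  std::vector<Seg> out;
  out.reserve(a.segs.size() + b.segs.size());
  size_t i = 0, j = 0;
  const std::vector<Seg>& A = a.segs;
  const std::vector<Seg>& B = b.segs;
  std::vector<double> cuts;
  cuts.reserve(2 * (A.size() + B.size()));
  for (const Seg& s : A) { cuts.push_back(s.l); cuts.push_back(s.r); }
  for (const Seg& s : B) { cuts.push_back(s.l); cuts.push_back(s.r); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    double l = cuts[c], r = cuts[c + 1];
    double mid = 0.5 * (l + r);
    while (i < A.size() && A[i].r <= mid) ++i;
    while (j < B.size() && B[j].r <= mid) ++j;
    bool inA = i < A.size() && A[i].l <= mid && mid < A[i].r;
    bool inB = j < B.size() && B[j].l <= mid && mid < B[j].r;
    if (!inA && !inB) continue;
    Bits d = inA ? A[i].d : B[j].d;
    if (inA && inB) d.orin(B[j].d);
    if (d.count() == nsamp) continue;            // local MRCA reached
    if (!out.empty() && out.back().r == l && out.back().d == d)
      out.back().r = r;
    else
      out.push_back(Seg{l, r, d});
  }
  a.segs.swap(out);
  b.segs.clear();
  b.alive = false;
}

// Split lineage material at breakpoint x: < x stays, >= x returned.
static std::vector<Seg> split_segs(std::vector<Seg>& segs, double x) {
  std::vector<Seg> left, right;
  for (Seg& s : segs) {
    if (s.r <= x) left.push_back(std::move(s));
    else if (s.l >= x) right.push_back(std::move(s));
    else {
      left.push_back(Seg{s.l, x, s.d});
      right.push_back(Seg{x, s.r, s.d});
    }
  }
  segs.swap(left);
  return right;
}

struct Site { double pos; Bits d; };

// place nm mutations uniformly over the lineage's material
static void place_mutations(const Lin& x, int nm, double tot,
                            std::vector<Site>& sites) {
  for (int m = 0; m < nm; ++m) {
    double u = R::unif_rand() * tot;
    for (const Seg& s : x.segs) {
      double w = s.r - s.l;
      if (u < w) { sites.push_back(Site{s.l + u, s.d}); break; }
      u -= w;
    }
  }
}

static void drop_mutations_dt(const Lin& x, double mu, double dt,
                              std::vector<Site>& sites) {
  double tot = mat_len(x);
  if (tot <= 0.0) return;
  int nm = (int) R::rpois(mu * tot * dt);
  if (nm > 0) place_mutations(x, nm, tot, sites);
}

// Trajectory-conditioned two-deme coalescent for a sample of n1 + n2
// haplotypes over [0, L). focal_pos < 0 runs a plain neutral coalescent.
// classes gives the focal allele (1 = derived) of each sampled haplotype;
// K1/K2 are derived copy counts per generation before present (0 beyond the
// origin); twoN1/twoN2/mig describe the demography per generation (clamped
// beyond their length); the per-generation phase runs to G_pergen (extended
// while derived lineages remain), after which a continuous-time single-deme
// phase with piecewise-constant epochs (ep_g, ep_2N) finishes the
// genealogy. mu and rec are per-bp per-(rescaled-)generation rates.
// [[Rcpp::export]]
List cpp_coalescent(int n1, int n2, double L, double focal_pos,
                    IntegerVector classes, double mu, double rec,
                    IntegerVector K1, IntegerVector K2,
                    IntegerVector twoN1, IntegerVector twoN2,
                    NumericVector mig, int G_split, int G_pergen,
                    IntegerVector ep_g, IntegerVector ep_2N) {
  const int n = n1 + n2;
  const int words = (n + 63) / 64;
  const bool focal = focal_pos >= 0.0;
  const int lenN = twoN1.size();
  const int lenK = K1.size();
  std::vector<Site> sites;
  std::vector<Lin> lins;
  lins.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Lin x;
    x.deme = i < n1 ? 0 : 1;
    x.cls = focal ? classes[i] : 0;
    x.alive = true;
    Bits d(words); d.set(i);
    x.segs.push_back(Seg{0.0, L, d});
    lins.push_back(std::move(x));
  }

  auto Kat = [&](int g, int deme) -> int {
    if (g >= lenK) return 0;
    return deme == 0 ? K1[g] : K2[g];
  };
  auto twoNat = [&](int g, int deme) -> int {
    int gc = clampidx(g, lenN);
    return deme == 0 ? twoN1[gc] : twoN2[gc];
  };

  // reusable per-generation buffers
  std::vector<int> alive_idx, bucket[4];
  std::vector<double> cum_len, cum_span;
  std::vector<std::pair<long, int>> parents;

  int g = 0;
  const int hard_cap = 2000000;
  bool have_derived = focal;
  while (g < hard_cap) {
    int gp = g + 1;  // parent generation

    // periodically drop dead entries so per-generation passes stay O(alive)
    if ((g & 31) == 0 && lins.size() > 32) {
      size_t nalive = 0;
      for (const Lin& x : lins) if (x.alive) ++nalive;
      if (lins.size() > 2 * nalive) {
        std::vector<Lin> keep;
        keep.reserve(nalive);
        for (Lin& x : lins) if (x.alive) keep.push_back(std::move(x));
        lins.swap(keep);
      }
    }

    // single pass: alive lineages, material lengths, spans, class counts
    alive_idx.clear(); cum_len.clear(); cum_span.clear();
    double T = 0.0, S = 0.0;
    int nder = 0;
    for (size_t ii = 0; ii < lins.size(); ++ii) {
      Lin& x = lins[ii];
      if (!x.alive) continue;
      if (x.segs.empty()) { x.alive = false; continue; }
      alive_idx.push_back((int) ii);
      T += mat_len(x);
      double lo = x.segs.front().l, hi = x.segs.back().r;
      if (focal) { lo = std::min(lo, focal_pos); hi = std::max(hi, focal_pos); }
      S += hi - lo;
      cum_len.push_back(T);
      cum_span.push_back(S);
      if (x.cls == 1) ++nder;
    }
    have_derived = focal && nder > 0;
    if (!(g < G_pergen || have_derived)) break;
    if (alive_idx.empty() || T <= 0.0) break;

    // mutations: one Poisson on the total material
    int nm = (int) R::rpois(mu * T);
    for (int m = 0; m < nm; ++m) {
      double u = R::unif_rand() * T;
      size_t j = std::lower_bound(cum_len.begin(), cum_len.end(), u) -
                 cum_len.begin();
      if (j >= alive_idx.size()) j = alive_idx.size() - 1;
      const Lin& x = lins[alive_idx[j]];
      double off = u - (j == 0 ? 0.0 : cum_len[j - 1]);
      for (const Seg& s : x.segs) {
        double w = s.r - s.l;
        if (off < w) { sites.push_back(Site{s.l + off, s.d}); break; }
        off -= w;
      }
    }

    // recombinations: one Poisson on the total span
    int nr = (int) R::rpois(rec * S);
    for (int e = 0; e < nr; ++e) {
      double u = R::unif_rand() * S;
      size_t j = std::lower_bound(cum_span.begin(), cum_span.end(), u) -
                 cum_span.begin();
      if (j >= alive_idx.size()) j = alive_idx.size() - 1;
      int id = alive_idx[j];
      if (!lins[id].alive || lins[id].segs.empty()) continue;
      double lo = lins[id].segs.front().l, hi = lins[id].segs.back().r;
      if (focal) { lo = std::min(lo, focal_pos); hi = std::max(hi, focal_pos); }
      double bp = lo + R::unif_rand() * (hi - lo);
      std::vector<Seg> rightm = split_segs(lins[id].segs, bp);
      int d = lins[id].deme;
      int twoN = twoNat(gp, d);
      double pD = twoN > 0 ? (double) Kat(gp, d) / twoN : 0.0;
      int newcls = (focal && R::unif_rand() < pD) ? 1 : 0;
      bool focal_right = focal && focal_pos >= bp;
      if (focal_right) {
        // focal travels with the right part: it keeps the original class
        std::vector<Seg> leftm;
        leftm.swap(lins[id].segs);
        lins[id].segs.swap(rightm);
        if (!leftm.empty()) {
          Lin nx; nx.deme = d; nx.cls = newcls; nx.alive = true;
          nx.segs.swap(leftm);
          lins.push_back(std::move(nx));   // may reallocate: use indices only
        }
      } else {
        if (!rightm.empty()) {
          Lin nx; nx.deme = d; nx.cls = newcls; nx.alive = true;
          nx.segs.swap(rightm);
          lins.push_back(std::move(nx));
        }
      }
      if (lins[id].segs.empty()) lins[id].alive = false;  // bare focal side
    }

    // deme merge at the split
    if (gp >= G_split)
      for (Lin& x : lins) if (x.alive) x.deme = 0;

    // migration (backward) during the two-deme era
    if (gp < G_split) {
      for (Lin& x : lins) {
        if (!x.alive) continue;
        int d = x.deme, o = 1 - d;
        double m = mig[clampidx(gp, lenN)];
        if (m <= 0.0) continue;
        // class frequencies, not counts: a fraction m of either deme's gene
        // pool immigrated in the forward direction regardless of deme size
        double Nd = twoNat(gp, d), No = twoNat(gp, o);
        double xs, xo;
        if (focal && x.cls == 1) {
          xs = Kat(gp, d) / Nd; xo = Kat(gp, o) / No;
        } else {
          xs = (Nd - Kat(gp, d)) / Nd;
          xo = (No - Kat(gp, o)) / No;
        }
        double num = m * xo, den = (1.0 - m) * xs + m * xo;
        if (den <= 0.0) continue;
        if (R::unif_rand() < num / den) x.deme = o;
      }
      // forced migration: derived lineage where the allele is absent
      if (focal)
        for (Lin& x : lins)
          if (x.alive && x.cls == 1 && Kat(gp, x.deme) == 0 &&
              Kat(gp, 1 - x.deme) > 0)
            x.deme = 1 - x.deme;
    }

    // origin: derived class extinct everywhere at the parent generation.
    // Remaining derived lineages have already been forced down to one per
    // carrying deme by the K = 1 coalescence step; the mutation event turns
    // them into ordinary ancestral-class lineages (one per onset deme).
    if (focal) {
      int ktot = Kat(gp, 0) + (gp < G_split ? Kat(gp, 1) : 0);
      if (ktot == 0)
        for (Lin& x : lins)
          if (x.alive && x.cls == 1) x.cls = 0;
    }

    // coalescence: common parents within (deme, class)
    for (int b = 0; b < 4; ++b) bucket[b].clear();
    for (size_t ii = 0; ii < lins.size(); ++ii)
      if (lins[ii].alive)
        bucket[lins[ii].deme * 2 + lins[ii].cls].push_back((int) ii);
    for (int b = 0; b < 4; ++b) {
      std::vector<int>& idx = bucket[b];
      if (idx.size() < 2) continue;
      int d = b / 2, c = b % 2;
      long Kg = (c == 1) ? Kat(gp, d) : (long) twoNat(gp, d) - Kat(gp, d);
      if (Kg < 1) Kg = 1;
      parents.clear();
      for (int id : idx) {
        long pidx = (long) (R::unif_rand() * (double) Kg);
        if (pidx >= Kg) pidx = Kg - 1;
        parents.push_back(std::make_pair(pidx, id));
      }
      std::sort(parents.begin(), parents.end());
      for (size_t q = 1; q < parents.size(); ++q)
        if (parents[q].first == parents[q - 1].first) {
          // the survivor of an earlier merge in this run was written back,
          // so parents[q-1].second is always alive
          int tgt = parents[q - 1].second;
          merge_lineages(lins[tgt], lins[parents[q].second], n);
          parents[q].second = tgt;
        }
    }
    ++g;
  }

  // ---- continuous-time single-deme phase (piecewise-constant sizes) ----
  {
    std::vector<Lin> keep;
    for (Lin& x : lins) if (x.alive && !x.segs.empty()) keep.push_back(std::move(x));
    lins.swap(keep);
  }
  double t = (double) g;
  const int nep = ep_g.size();
  int guard = 0;
  while (lins.size() >= 2 && ++guard < 5000000) {
    int e = 0;
    while (e + 1 < nep && t >= (double) ep_g[e + 1]) ++e;
    double twoN = (double) ep_2N[e];
    double next_boundary = (e + 1 < nep) ? (double) ep_g[e + 1] : R_PosInf;
    size_t k = lins.size();
    double coal_rate = (double) k * (k - 1) / 2.0 / twoN;
    double rec_rate = 0.0;
    std::vector<double> spans(k);
    for (size_t i = 0; i < k; ++i) {
      spans[i] = lins[i].segs.back().r - lins[i].segs.front().l;
      rec_rate += rec * spans[i];
    }
    double tot = coal_rate + rec_rate;
    if (tot <= 0.0) break;
    double dt = R::exp_rand() / tot;
    if (t + dt >= next_boundary) {             // cross into the next epoch
      for (Lin& x : lins) drop_mutations_dt(x, mu, next_boundary - t, sites);
      t = next_boundary;
      continue;
    }
    for (Lin& x : lins) drop_mutations_dt(x, mu, dt, sites);
    t += dt;
    if (R::unif_rand() < coal_rate / tot) {
      size_t i = (size_t) (R::unif_rand() * k); if (i >= k) i = k - 1;
      size_t j = (size_t) (R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      merge_lineages(lins[i], lins[j], n);
      std::vector<Lin> keep;
      for (Lin& x : lins) if (x.alive && !x.segs.empty()) keep.push_back(std::move(x));
      lins.swap(keep);
    } else {
      double u = R::unif_rand() * rec_rate;
      size_t i = 0;
      for (; i < k; ++i) { if (u < rec * spans[i]) break; u -= rec * spans[i]; }
      if (i >= k) i = k - 1;
      double bp = lins[i].segs.front().l + (u / rec);
      std::vector<Seg> rightm = split_segs(lins[i].segs, bp);
      if (!rightm.empty() && !lins[i].segs.empty()) {
        Lin nx; nx.deme = 0; nx.cls = 0; nx.alive = true;
        nx.segs.swap(rightm);
        lins.push_back(std::move(nx));
      } else if (!rightm.empty()) {
        lins[i].segs.swap(rightm);
      }
    }
  }

  // ---- emit sites ----
  std::sort(sites.begin(), sites.end(),
            [](const Site& a, const Site& b) { return a.pos < b.pos; });
  int Sn = (int) sites.size();
  NumericVector pos(Sn);
  IntegerMatrix mat(n, Sn);
  for (int sI = 0; sI < Sn; ++sI) {
    pos[sI] = sites[sI].pos;
    for (int i = 0; i < n; ++i)
      if (sites[sI].d.w[i >> 6] & (1ull << (i & 63))) mat(i, sI) = 1;
  }
  return List::create(_["positions"] = pos, _["matrix"] = mat);
}

// ---------------------------------------------------------------------------
// EHH decay outward from a core site for a fixed carrier set. Returns, for
// each direction, the EHH value at every site from the core to the region
// edge (first entry = the core itself), stopping early once EHH = 0. With
// pooled = false the carriers share the core allele and EHH starts at 1;
// with pooled = true identity includes the core allele itself, so EHH
// starts at the core-site homozygosity (the XP-EHH convention).
// [[Rcpp::export]]
List cpp_ehh_decay(IntegerMatrix mat, IntegerVector carriers, int core,
                   bool pooled = false) {
  int k = carriers.size();
  int S = mat.ncol();
  double pairs = (double) k * (k - 1) / 2.0;
  auto scan = [&](int step) {
    std::vector<double> out;
    std::vector<int> grp(k, 0), ng(k), cnt;
    if (pooled) {
      int n1c = 0;
      for (int i = 0; i < k; ++i) {
        grp[i] = mat(carriers[i], core);
        n1c += grp[i];
      }
      double hom = ((double) n1c * (n1c - 1) +
                    (double) (k - n1c) * (k - n1c - 1)) / 2.0;
      out.push_back(hom / pairs);
    } else {
      out.push_back(1.0);
    }
    for (int c = core + step; c >= 0 && c < S; c += step) {
      // refine groups by the allele at site c (order-preserving relabel)
      std::vector<std::pair<long, int>> keys(k);
      for (int i = 0; i < k; ++i)
        keys[i] = std::make_pair((long) grp[i] * 2 + mat(carriers[i], c), i);
      std::sort(keys.begin(), keys.end());
      int nn = 0;
      for (int i = 0; i < k; ++i) {
        if (i > 0 && keys[i].first != keys[i - 1].first) ++nn;
        ng[keys[i].second] = nn;
      }
      ++nn;
      grp = ng;
      cnt.assign(nn, 0);
      for (int i = 0; i < k; ++i) cnt[grp[i]]++;
      double hom = 0.0;
      for (int c2 : cnt) hom += (double) c2 * (c2 - 1) / 2.0;
      double e = hom / pairs;
      out.push_back(e);
      if (e <= 0.0) break;
    }
    return NumericVector(out.begin(), out.end());
  };
  return List::create(_["left"] = scan(-1), _["right"] = scan(+1));
}
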