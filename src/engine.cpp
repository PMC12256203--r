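// Compiled simulation core: runs the full annual cycle
// (reproduction -> competition -> immigration -> dispersal) over tmax
// steps for one replicate. All randomness comes from R's global RNG
// stream, so set.seed() on the R side makes whole runs reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  std::vector<int> patch, lineage;
  std::vector<double> topt, ttol, hopt, htol, pdisp, pglob;
  size_t size() const { return patch.size(); }
  void clear() {
    patch.clear(); lineage.clear();
    topt.clear(); ttol.clear(); hopt.clear(); htol.clear();
    pdisp.clear(); pglob.clear();
  }
  void reserve(size_t n) {
    patch.reserve(n); lineage.reserve(n);
    topt.reserve(n); ttol.reserve(n); hopt.reserve(n); htol.reserve(n);
    pdisp.reserve(n); pglob.reserve(n);
  }
  void push(int p, int lin, double to, double tt, double ho, double ht,
            double pd, double pg) {
    patch.push_back(p); lineage.push_back(lin);
    topt.push_back(to); ttol.push_back(tt);
    hopt.push_back(ho); htol.push_back(ht);
    pdisp.push_back(pd); pglob.push_back(pg);
  }
  void swap(Pop& o) {
    patch.swap(o.patch); lineage.swap(o.lineage);
    topt.swap(o.topt); ttol.swap(o.ttol);
    hopt.swap(o.hopt); htol.swap(o.htol);
    pdisp.swap(o.pdisp); pglob.swap(o.pglob);
  }
  void push_copy(const Pop& src, size_t i) {
    push(src.patch[i], src.lineage[i], src.topt[i], src.ttol[i],
         src.hopt[i], src.htol[i], src.pdisp[i], src.pglob[i]);
  }
};

// Gaussian niche with tolerance/fecundity trade-off. kden is the
// mismatch-denominator factor (1 or 2); inv2a2 = 1 / (2 * alpha^2).
inline double fert(double R0, double inv2a2, double kden,
                   double Tp, double Hp,
                   double to, double tt, double ho, double ht) {
  const double dt = Tp - to, dh = Hp - ho;
  return R0 * std::exp(-(dt * dt) / (kden * tt * tt)
                       - (dh * dh) / (kden * ht * ht)
                       - (tt * tt + ht * ht) * inv2a2);
}

struct Acc {  // running mean/variance via sum and sum of squares
  double s = 0.0, s2 = 0.0;
  long n = 0;
  void add(double x) { s += x; s2 += x * x; ++n; }
  double mean() const { return n ? s / n : NA_REAL; }
  double var() const {
    if (n < 2) return NA_REAL;
    double v = (s2 - s * s / n) / (n - 1);
    return v > 0 ? v : 0.0;
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_sim_cpp")]]
List run_sim_cpp(NumericMatrix t_base, NumericMatrix h_base, double G,
                 NumericVector eps, int tmax,
                 double R0, double alpha, double K, double Eimmi,
                 double Ttrend, double denom_factor,
                 bool record_summaries, int next_lineage0) {
  const int height = t_base.nrow(), width = t_base.ncol();
  const int npatch = width * height;
  const double a = (R0 - 1.0) / (K * R0);
  const double inv2a2 = 1.0 / (2.0 * alpha * alpha);

  // per-patch scaled attributes, indexed p = y * width + x
  std::vector<double> tb(npatch), hb(npatch);
  for (int y = 0; y < height; ++y)
    for (int x = 0; x < width; ++x) {
      tb[y * width + x] = G * t_base(y, x);
      hb[y * width + x] = G * h_base(y, x);
    }

  Pop pop, off;
  int next_lineage = next_lineage0;
  std::vector<int> L0(npatch, 0), noff;
  static const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

  const int ns_cols = 20;
  NumericMatrix summaries(record_summaries ? tmax : 0, ns_cols);

  for (int t = 1; t <= tmax; ++t) {
    const double eps_t = eps[t - 1];

    // (1) reproduction: Poisson(Efert) clonal offspring per adult
    noff.resize(pop.size());
    std::fill(L0.begin(), L0.end(), 0);
    for (size_t i = 0; i < pop.size(); ++i) {
      const int p = pop.patch[i];
      const double ef = fert(R0, inv2a2, denom_factor,
                             tb[p] + eps_t, hb[p],
                             pop.topt[i], pop.ttol[i],
                             pop.hopt[i], pop.htol[i]);
      noff[i] = (int) R::rpois(ef);
      L0[p] += noff[i];
    }

    // (2) competition: survival is trait-blind with per-offspring
    // probability SA = 1/(1 + a*L0), so the per-parent survivor count
    // is Binomial(noff_i, SA) — equivalent to independent
    // Bernoulli(SA) draws over the materialized offspring pool, with
    // the patch total exactly Binomial(L0, SA).
    off.clear();
    off.reserve(pop.size() + 64);
    for (size_t i = 0; i < pop.size(); ++i) {
      if (noff[i] == 0) continue;
      const double sa = 1.0 / (1.0 + a * L0[pop.patch[i]]);
      const int nsurv = (int) R::rbinom((double) noff[i], sa);
      for (int j = 0; j < nsurv; ++j) off.push_copy(pop, i);
    }
    pop.swap(off);

    // (3) external immigration: Poisson(Eimmi) fresh lineages per patch
    for (int p = 0; p < npatch; ++p) {
      const int nimm = (int) R::rpois(Eimmi);
      for (int j = 0; j < nimm; ++j)
        pop.push(p, next_lineage++,
                 R::rnorm(Ttrend, G), std::exp(R::norm_rand()),
                 R::rnorm(0.0, G), std::exp(R::norm_rand()),
                 unif_rand(), unif_rand());
    }

    // (4) dispersal of the new generation
    for (size_t i = 0; i < pop.size(); ++i) {
      if (unif_rand() > pop.pdisp[i]) continue;
      int x = pop.patch[i] % width, y = pop.patch[i] / width;
      if (unif_rand() <= pop.pglob[i]) {
        // global: uniform over the npatch-1 non-natal patches
        const int natal = pop.patch[i];
        int draw = (int) std::floor(unif_rand() * (npatch - 1));
        if (draw >= npatch - 1) draw = npatch - 2;  // guard u == 1
        pop.patch[i] = (draw >= natal) ? draw + 1 : draw;
      } else {
        // nearest neighbour: uniform over the 8 Moore cells, torus wrap
        int k = (int) std::floor(unif_rand() * 8.0);
        if (k > 7) k = 7;
        x = (x + dx[k] + width) % width;
        y = (y + dy[k] + height) % height;
        pop.patch[i] = y * width + x;
      }
    }

    // (5) landscape-wide summary of the settled new generation,
    //     fitness evaluated at this step's realized attributes
    if (record_summaries) {
      Acc ac[9];
      for (size_t i = 0; i < pop.size(); ++i) {
        const int p = pop.patch[i];
        const double ef = fert(R0, inv2a2, denom_factor,
                               tb[p] + eps_t, hb[p],
                               pop.topt[i], pop.ttol[i],
                               pop.hopt[i], pop.htol[i]);
        const double trade =
            std::exp(-(pop.ttol[i] * pop.ttol[i] +
                       pop.htol[i] * pop.htol[i]) * inv2a2);
        ac[0].add(pop.topt[i]); ac[1].add(pop.ttol[i]);
        ac[2].add(pop.hopt[i]); ac[3].add(pop.htol[i]);
        ac[4].add(pop.pdisp[i]); ac[5].add(pop.pglob[i]);
        ac[6].add(ef);
        ac[7].add(ef / (R0 * trade));
        ac[8].add(ef / R0);
      }
      const int r = t - 1;
      summaries(r, 0) = t;
      summaries(r, 1) = (double) pop.size();
      for (int q = 0; q < 9; ++q) {
        summaries(r, 2 + 2 * q) = ac[q].mean();
        summaries(r, 3 + 2 * q) = ac[q].var();
      }
    }

    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // final census: base (time-invariant) and fluctuation-realized T;
  // fitness metrics computed from the base attribute
  const double eps_final = tmax >= 1 ? eps[tmax - 1] : 0.0;
  const size_t n = pop.size();
  NumericMatrix census(n, 15);
  for (size_t i = 0; i < n; ++i) {
    const int p = pop.patch[i];
    const double ef = fert(R0, inv2a2, denom_factor, tb[p], hb[p],
                           pop.topt[i], pop.ttol[i],
                           pop.hopt[i], pop.htol[i]);
    const double trade = std::exp(-(pop.ttol[i] * pop.ttol[i] +
                                    pop.htol[i] * pop.htol[i]) * inv2a2);
    census(i, 0) = p % width;           // x
    census(i, 1) = p / width;           // y
    census(i, 2) = pop.lineage[i];
    census(i, 3) = pop.topt[i];
    census(i, 4) = pop.ttol[i];
    census(i, 5) = pop.hopt[i];
    census(i, 6) = pop.htol[i];
    census(i, 7) = pop.pdisp[i];
    census(i, 8) = pop.pglob[i];
    census(i, 9) = tb[p];               // Tpatch_base
    census(i, 10) = tb[p] + eps_final;  // Tpatch_realized
    census(i, 11) = hb[p];              // Hpatch
    census(i, 12) = ef;
    census(i, 13) = ef / (R0 * trade);
    census(i, 14) = ef / R0;
  }

  return List::create(_["summaries"] = summaries, _["census"] = census,
                      _["next_lineage_id"] = next_lineage);
}

// Scalar fertility, exposed for cross-checking the compiled engine's
// formula against the R implementation.
// [[Rcpp::export(name = ".fertility_cpp")]]
NumericVector fertility_cpp(NumericVector Tpatch, NumericVector Hpatch,
                            NumericVector Topt, NumericVector Ttol,
                            NumericVector Hopt, NumericVector Htol,
                            double R0, double alpha, double denom_factor) {
  const double inv2a2 = 1.0 / (2.0 * alpha * alpha);
  const R_xlen_t n = Topt.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = fert(R0, inv2a2, denom_factor, Tpatch[i], Hpatch[i],
                  Topt[i], Ttol[i], Hopt[i], Htol[i]);
  return out;
}
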