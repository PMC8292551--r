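#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Exact event-driven simulation of individual life histories under the
// clonal-expansion semantics used by the analytic hazard engine:
//   BE stem cells (continuous count N, fixed) spawn one-hit cells at mu0 each;
//   one-hit cells persist and spawn premalignant founders at mu1;
//   premalignant cells divide/die/spawn-malignant at alphaP/betaP/mu2
//   (parent persists on spawning); malignant cells divide/die/trigger
//   detection at alphaM/betaM/rho (size-based detection).
// Randomness comes from a counter-seeded xoshiro256++ stream per individual,
// so histories are reproducible and independent of simulation order.

namespace {

struct Rng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1); never exactly 0 (safe for log)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }

  double expdraw() { return -std::log(unif()); }

  double normal() {
    // Box-Muller (polar form)
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    return u * std::sqrt(-2.0 * std::log(s2) / s2);
  }

  // Marsaglia-Tsang gamma(shape, 1); shape < 1 via boosting
  double gamma(double shape) {
    if (shape < 1.0) {
      double u = unif();
      return gamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  double beta(double a, double b) {
    double x = gamma(a);
    double y = gamma(b);
    return x / (x + y);
  }
};

// invert a non-decreasing cumulative hazard tabulated on a uniform grid
double invert_cumhaz(const std::vector<double> &grid,
                     const std::vector<double> &Lam, double target) {
  size_t n = Lam.size();
  size_t lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (Lam[mid] < target) lo = mid; else hi = mid;
  }
  double dL = Lam[hi] - Lam[lo];
  double frac = dL > 0.0 ? (target - Lam[lo]) / dL : 1.0;
  return grid[lo] + frac * (grid[hi] - grid[lo]);
}

} // namespace

// [[Rcpp::export]]
Rcpp::DataFrame sim_cohort_cpp(int n,
                               Rcpp::NumericVector params,   // mu0 mu1 aP bP mu2 aM bM rho
                               Rcpp::NumericVector age_grid,
                               Rcpp::NumericVector Lambda,
                               double beta_a, double beta_b,
                               double length_max, double cells_per_cm,
                               double max_age,
                               double master_seed,
                               double event_cap) {
  const double mu0 = params[0], mu1 = params[1];
  const double aP = params[2], bP = params[3], mu2 = params[4];
  const double aM = params[5], bM = params[6], rho = params[7];

  std::vector<double> grid(age_grid.begin(), age_grid.end());
  std::vector<double> Lam(Lambda.begin(), Lambda.end());
  const double Lam_max = Lam.back();

  Rcpp::NumericVector be_onset(n, NA_REAL), be_length(n, NA_REAL),
      n_stem(n, NA_REAL), oac_age(n, NA_REAL), n_events(n);

  const uint64_t master = static_cast<uint64_t>(master_seed);

  for (int i = 0; i < n; ++i) {
    uint64_t stream = master ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(i + 1));
    Rng rng(stream);

    // BE onset by inversion of the cumulative onset hazard
    double target = rng.expdraw();
    if (target >= Lam_max) { n_events[i] = 0; continue; }
    double t_be = invert_cumhaz(grid, Lam, target);
    if (t_be >= max_age) { n_events[i] = 0; continue; }
    be_onset[i] = t_be;

    double L = length_max * rng.beta(beta_a, beta_b);
    double N = cells_per_cm * L;   // stem-cell count, continuous by design
    be_length[i] = L;
    n_stem[i] = N;

    double t = t_be;
    double n1 = 0.0, nP = 0.0, nM = 0.0;
    double events = 0.0;
    const double a_stem = N * mu0;

    for (;;) {
      double aSpawnP = n1 * mu1;
      double aDivP = nP * aP, aDieP = nP * bP, aSpawnM = nP * mu2;
      double aDivM = nM * aM, aDieM = nM * bM, aDet = nM * rho;
      double total = a_stem + aSpawnP + aDivP + aDieP + aSpawnM +
                     aDivM + aDieM + aDet;
      if (total <= 0.0) break;
      t += rng.expdraw() / total;
      if (t >= max_age) break;
      if (++events > event_cap)
        Rcpp::stop("event cap exceeded for individual %d (mu0=%g, alphaP=%g, betaP=%g)",
                   i + 1, mu0, aP, bP);
      double r = rng.unif() * total;
      if ((r -= a_stem) < 0.0)        { n1 += 1.0; continue; }
      if ((r -= aSpawnP) < 0.0)       { nP += 1.0; continue; }
      if ((r -= aDivP) < 0.0)         { nP += 1.0; continue; }
      if ((r -= aDieP) < 0.0)         { nP -= 1.0; continue; }
      if ((r -= aSpawnM) < 0.0)       { nM += 1.0; continue; }
      if ((r -= aDivM) < 0.0)         { nM += 1.0; continue; }
      if ((r -= aDieM) < 0.0)         { nM -= 1.0; continue; }
      oac_age[i] = t;                 // detection
      break;
    }
    n_events[i] = events;
  }

  return Rcpp::DataFrame::create(
      Rcpp::Named("id") = Rcpp::seq_len(n),
      Rcpp::Named("be_onset_age") = be_onset,
      Rcpp::Named("be_length") = be_length,
      Rcpp::Named("n_stem_cells") = n_stem,
      Rcpp::Named("oac_detection_age") = oac_age,
      Rcpp::Named("n_events") = n_events);
}
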