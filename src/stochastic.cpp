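#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Self-contained counter-seeded RNG (splitmix64 -> xoshiro256++) so that
// trajectories are bit-reproducible across platforms and standard libraries,
// and per-run seeds can be split from a master seed without correlation.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): never exactly 0 so log() is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rexp(double rate) { return -std::log(unif()) / rate; }
  // Knuth's product-of-uniforms Poisson, chunked so exp(-mu) never underflows
  inline int rpois(double mu) {
    int total = 0;
    while (mu > 500.0) {
      total += rpois_knuth(500.0);
      mu -= 500.0;
    }
    return total + rpois_knuth(mu);
  }
  inline int rpois_knuth(double mu) {
    if (mu <= 0.0) return 0;
    const double L = std::exp(-mu);
    int k = 0;
    double p = 1.0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// derive a per-run seed from a master seed and a run index
static inline uint64_t split_seed(uint64_t master, uint64_t index) {
  uint64_t x = master ^ (0xD2B74407B1CE6E93ULL * (index + 1));
  return splitmix64(x);
}

static inline void compute_propensities(const IntegerMatrix &stoich,
                                        const NumericVector &rates,
                                        const IntegerMatrix &orders,
                                        const std::vector<double> &x,
                                        std::vector<double> &a) {
  const int n_sp = stoich.nrow(), n_rx = stoich.ncol();
  for (int j = 0; j < n_rx; ++j) {
    double aj = rates[j];
    for (int i = 0; i < n_sp && aj > 0; ++i) {
      int k = orders(i, j);
      for (int q = 0; q < k; ++q) aj *= (x[i] - q);
    }
    a[j] = aj > 0 ? aj : 0.0;
  }
}

// [[Rcpp::export]]
List ssa_simulate_cpp(IntegerMatrix stoich, NumericVector rates,
                      IntegerMatrix orders, IntegerVector initial,
                      double duration, int n_points, double seed) {
  const int n_sp = stoich.nrow(), n_rx = stoich.ncol();
  Xoshiro rng((uint64_t)seed);
  std::vector<double> x(initial.begin(), initial.end());
  std::vector<double> a(n_rx);
  NumericVector times(n_points + 1);
  NumericMatrix states(n_points + 1, n_sp);
  for (int k = 0; k <= n_points; ++k) times[k] = duration * k / n_points;
  int next_rec = 0;
  double t = 0.0;
  bool absorbed = false;
  while (t < duration) {
    compute_propensities(stoich, rates, orders, x, a);
    double a0 = 0.0;
    for (int j = 0; j < n_rx; ++j) a0 += a[j];
    if (a0 <= 0.0) { absorbed = true; break; }
    double t_next = t + rng.rexp(a0);
    if (t_next > duration) break;
    // boundaries passed before the next event keep the current state
    while (next_rec <= n_points && times[next_rec] < t_next) {
      for (int i = 0; i < n_sp; ++i) states(next_rec, i) = x[i];
      ++next_rec;
    }
    t = t_next;
    double r = rng.unif() * a0, cum = 0.0;
    int j = n_rx - 1;
    for (int jj = 0; jj < n_rx; ++jj) {
      cum += a[jj];
      if (r <= cum) { j = jj; break; }
    }
    for (int i = 0; i < n_sp; ++i) x[i] += stoich(i, j);
  }
  while (next_rec <= n_points) {
    for (int i = 0; i < n_sp; ++i) states(next_rec, i) = x[i];
    ++next_rec;
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["absorbed"] = absorbed);
}

// one adaptive tau-leap advance over [t0, t1]; returns false on step underflow.
// Reaction channels that change any low-copy species (< n_crit copies) are
// treated as critical: they fire as exact single events (next-event time
// exponential in their summed propensity) while the remaining channels leap
// with Poisson counts — a species-partitioned hybrid that removes the
// small-number leaping bias for both consumption and production.
static bool tauleap_interval(const IntegerMatrix &stoich,
                             const NumericVector &rates,
                             const IntegerMatrix &orders,
                             std::vector<double> &x,
                             double t0, double t1, double eps,
                             const std::vector<double> &gi, Xoshiro &rng) {
  const int n_sp = stoich.nrow(), n_rx = stoich.ncol();
  const double n_crit = 10.0;
  std::vector<double> a(n_rx);
  std::vector<int> k(n_rx);
  std::vector<bool> crit(n_rx);
  double t = t0;
  while (t < t1 - 1e-9) {
    compute_propensities(stoich, rates, orders, x, a);
    double a0 = 0.0;
    for (int j = 0; j < n_rx; ++j) a0 += a[j];
    if (a0 <= 0.0) return true;  // frozen state, nothing can fire
    double a0c = 0.0;
    for (int j = 0; j < n_rx; ++j) {
      bool cj = false;
      if (a[j] > 0) {
        for (int i = 0; i < n_sp; ++i) {
          if (stoich(i, j) != 0 && x[i] < n_crit) { cj = true; break; }
        }
      }
      crit[j] = cj;
      if (cj) a0c += a[j];
    }
    // leap-size selection over the non-critical channels only
    double tau = t1 - t;
    for (int i = 0; i < n_sp; ++i) {
      double mu = 0.0, s2 = 0.0;
      for (int j = 0; j < n_rx; ++j) {
        if (crit[j]) continue;
        double v = stoich(i, j);
        mu += v * a[j];
        s2 += v * v * a[j];
      }
      double bound = eps * x[i] / gi[i];
      if (bound < 1.0) bound = 1.0;
      if (mu != 0.0) tau = std::min(tau, bound / std::fabs(mu));
      if (s2 > 0.0)  tau = std::min(tau, bound * bound / s2);
    }
    if (t1 - t < 1e-6) { t = t1; break; }  // final sliver of the interval
    double tau2 = (a0c > 0.0) ? rng.rexp(a0c) : std::numeric_limits<double>::infinity();
    // draw counts; halve the step (and redraw) on negative excursions
    for (;;) {
      if (tau < 1e-7) return false;
      bool fire_crit = tau2 <= tau;
      double step = fire_crit ? tau2 : tau;
      if (step > t1 - t) { fire_crit = false; step = t1 - t; }
      std::vector<double> xn(x);
      for (int j = 0; j < n_rx; ++j) {
        if (crit[j]) continue;
        k[j] = rng.rpois(a[j] * step);
        if (k[j] == 0) continue;
        for (int i = 0; i < n_sp; ++i) xn[i] += (double)k[j] * stoich(i, j);
      }
      if (fire_crit) {
        double r = rng.unif() * a0c, cum = 0.0;
        int jc = -1;
        for (int j = 0; j < n_rx; ++j) {
          if (!crit[j]) continue;
          cum += a[j];
          jc = j;
          if (r <= cum) break;
        }
        for (int i = 0; i < n_sp; ++i) xn[i] += stoich(i, jc);
      }
      bool ok = true;
      for (int i = 0; i < n_sp; ++i) if (xn[i] < 0) { ok = false; break; }
      if (ok) { x = xn; t += step; break; }
      tau *= 0.5;
    }
  }
  return true;
}

static std::vector<double> order_weights(const IntegerMatrix &orders) {
  const int n_sp = orders.nrow(), n_rx = orders.ncol();
  std::vector<double> gi(n_sp, 1.0);
  for (int j = 0; j < n_rx; ++j) {
    int tot = 0;
    for (int i = 0; i < n_sp; ++i) tot += orders(i, j);
    for (int i = 0; i < n_sp; ++i) {
      if (orders(i, j) > 0 && tot > (int)gi[i]) gi[i] = tot;
    }
  }
  return gi;
}

// [[Rcpp::export]]
List tauleap_simulate_cpp(IntegerMatrix stoich, NumericVector rates,
                          IntegerMatrix orders, IntegerVector initial,
                          double duration, int n_intervals, double eps,
                          double seed) {
  const int n_sp = stoich.nrow();
  Xoshiro rng((uint64_t)seed);
  std::vector<double> x(initial.begin(), initial.end());
  std::vector<double> gi = order_weights(orders);
  NumericVector times(n_intervals + 1);
  NumericMatrix states(n_intervals + 1, n_sp);
  for (int i = 0; i < n_sp; ++i) states(0, i) = x[i];
  times[0] = 0.0;
  double h = duration / n_intervals;
  for (int k = 1; k <= n_intervals; ++k) {
    if (!tauleap_interval(stoich, rates, orders, x, (k - 1) * h, k * h, eps,
                          gi, rng)) {
      stop("tau-leap step underflow (tau < 1e-6 min) near t = %f min",
           (k - 1) * h);
    }
    times[k] = k * h;
    for (int i = 0; i < n_sp; ++i) states(k, i) = x[i];
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["absorbed"] = false);
}

// [[Rcpp::export]]
NumericMatrix ensemble_terminal_cpp(IntegerMatrix stoich, NumericVector rates,
                                    IntegerMatrix orders, IntegerVector initial,
                                    double duration, int n_intervals,
                                    double eps, int n, double master_seed,
                                    std::string method) {
  const int n_sp = stoich.nrow(), n_rx = stoich.ncol();
  NumericMatrix out(n, n_sp);
  std::vector<double> gi = order_weights(orders);
  for (int run = 0; run < n; ++run) {
    Xoshiro rng(split_seed((uint64_t)master_seed, (uint64_t)run));
    std::vector<double> x(initial.begin(), initial.end());
    if (method == "tauleap") {
      double h = duration / n_intervals;
      for (int k = 1; k <= n_intervals; ++k) {
        if (!tauleap_interval(stoich, rates, orders, x, (k - 1) * h, k * h,
                              eps, gi, rng)) {
          stop("tau-leap step underflow in ensemble run %d", run + 1);
        }
      }
    } else {  // exact SSA
      std::vector<double> a(n_rx);
      double t = 0.0;
      while (t < duration) {
        compute_propensities(stoich, rates, orders, x, a);
        double a0 = 0.0;
        for (int j = 0; j < n_rx; ++j) a0 += a[j];
        if (a0 <= 0.0) break;
        double dt = rng.rexp(a0);
        if (t + dt > duration) break;
        t += dt;
        double r = rng.unif() * a0, cum = 0.0;
        int j = n_rx - 1;
        for (int jj = 0; jj < n_rx; ++jj) {
          cum += a[jj];
          if (r <= cum) { j = jj; break; }
        }
        for (int i = 0; i < n_sp; ++i) x[i] += stoich(i, j);
      }
    }
    for (int i = 0; i < n_sp; ++i) out(run, i) = x[i];
  }
  return out;
}
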