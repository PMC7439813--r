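#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fast counter-free normal generator (xoshiro256++ + Box-Muller), seeded
// from the R RNG so all randomness remains reproducible from set.seed().
// R's norm_rand() is the bottleneck when a fresh background draw is needed
// for every neuron at every 1-ms step.
struct FastNormal {
  uint64_t s[4];
  double spare;
  bool has_spare;
  explicit FastNormal() : has_spare(false) {
    // splitmix64 over a 64-bit seed drawn from the R RNG
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                    (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next_u64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double next_unif() {  // in (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double next_norm() {
    if (has_spare) { has_spare = false; return spare; }
    const double u = next_unif(), v = next_unif();
    const double r = std::sqrt(-2.0 * std::log(u));
    const double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Transfer-function evaluation (network-scaled parameters).
// kind: 0 = none, 1 = linear, 2 = sigmoid, 3 = exponential.
static inline double eval_transfer(int kind, const double *g, double r) {
  switch (kind) {
  case 0: return 1.0;
  case 1: { double v = 1.0 - g[0] * r; return v > 0.0 ? (v < 1.0 ? v : 1.0) : 0.0; }
  case 2: return 1.0 / (1.0 + std::exp(g[1] * (r - g[2])));
  default: return std::exp(-g[3] * r);
  }
}

// Full-size excitatory-inhibitory rate network with a global release factor
// and the BCM rule on E->E weights. Forward Euler; rates rectified and
// saturated at r_max each step. Indices are 0-based; presynaptic partners
// of neuron i are the i-th column of the index matrices.
// [[Rcpp::export]]
List simulate_rate_cpp(IntegerMatrix exc_in_E, IntegerMatrix inh_in_E,
                       IntegerMatrix exc_in_I, IntegerMatrix inh_in_I,
                       NumericMatrix W_EE,
                       NumericVector r_E, NumericVector r_I,
                       double p0, NumericVector r_bar,
                       double w_EI, double w_IE, double w_II,
                       double I_mean, double noise_sd, bool noise_static,
                       double r_max,
                       double tau_E, double tau_I, double tau_p,
                       int kind, NumericVector g_par,
                       double kappa, double eta, double w0,
                       double plast_scale,
                       double tau_w, double tau_c, double w_max,
                       double duration, double dt,
                       bool plasticity, double warmup,
                       int record_every, int neuron_every,
                       bool stop_on_runaway) {
  const int NE = r_E.size(), NI = r_I.size();
  const int kE = exc_in_E.nrow(), kI = inh_in_E.nrow();
  const int kEI = exc_in_I.nrow(), kII = inh_in_I.nrow();
  const long n_steps = (long)std::lround(duration / dt);

  std::vector<double> rE(r_E.begin(), r_E.end());
  std::vector<double> rI(r_I.begin(), r_I.end());
  std::vector<double> rEn(NE), rIn(NI);
  std::vector<double> rb(r_bar.begin(), r_bar.end());
  std::vector<double> W(W_EE.begin(), W_EE.end());
  const int *preE = exc_in_E.begin();
  const int *preI = inh_in_E.begin();
  const int *preEI = exc_in_I.begin();
  const int *preII = inh_in_I.begin();
  const double *g = g_par.begin();
  double p = p0;

  FastNormal rng;
  std::vector<double> Ibg(NE, I_mean);
  if (noise_static && noise_sd > 0) {
    for (int i = 0; i < NE; ++i) Ibg[i] = I_mean + noise_sd * rng.next_norm();
  }

  const double aE = dt / tau_E, aI = dt / tau_I, aP = dt / tau_p;
  const double aC = dt / tau_c;
  // per-synapse BCM coefficient; plast_scale (= 1/(c N_E)) keeps the mean
  // population weight on the population-level plasticity timescale
  const double plast_coef =
    (dt / tau_w) * eta * w0 * plast_scale / (kappa * kappa * kappa);
  const long warm_steps = std::isfinite(warmup)
    ? (long)std::lround(warmup / dt) : n_steps + 1;

  const long n_rec = n_steps / record_every + 1;
  NumericMatrix trace(n_rec, 6);
  long rec_i = 0;
  NumericMatrix ratesE;
  NumericVector rates_time;
  long nrec_i = 0;
  if (neuron_every > 0) {
    long n_nrec = n_steps / neuron_every + 1;
    ratesE = NumericMatrix(n_nrec, NE);
    rates_time = NumericVector(n_nrec);
  }

  auto record = [&](double t) {
    double s = 0, s2 = 0, si = 0, sw = 0;
    for (int i = 0; i < NE; ++i) { s += rE[i]; s2 += rE[i] * rE[i]; }
    for (int i = 0; i < NI; ++i) si += rI[i];
    for (size_t e = 0; e < W.size(); ++e) sw += W[e];
    double m = s / NE;
    double var = s2 / NE - m * m;
    trace(rec_i, 0) = t;
    trace(rec_i, 1) = m;
    trace(rec_i, 2) = std::sqrt(var > 0 ? var : 0);
    trace(rec_i, 3) = si / NI;
    trace(rec_i, 4) = p;
    trace(rec_i, 5) = sw / (double)W.size();
    ++rec_i;
    return m;
  };
  record(0.0);
  auto record_neuron = [&](double t) {
    for (int i = 0; i < NE; ++i) ratesE(nrec_i, i) = rE[i];
    rates_time[nrec_i] = t;
    ++nrec_i;
  };
  if (neuron_every > 0) record_neuron(0.0);

  bool runaway = false;
  double runaway_since = -1.0;

  for (long step = 1; step <= n_steps; ++step) {
    const bool plast_on = plasticity && (step - 1) >= warm_steps;

    // excitatory rates (and fused BCM update on the same pass)
    for (int i = 0; i < NE; ++i) {
      const int *pe = preE + (size_t)i * kE;
      double *wi = W.data() + (size_t)i * kE;
      double acc = 0.0;
      if (plast_on) {
        const double a = plast_coef * rE[i] * (rE[i] - rb[i] * rb[i] / kappa);
        for (int k = 0; k < kE; ++k) {
          const double rpre = rE[pe[k]];
          acc += wi[k] * rpre;
          double w = wi[k] + a * rpre;
          wi[k] = w < 0.0 ? 0.0 : (w > w_max ? w_max : w);
        }
      } else {
        for (int k = 0; k < kE; ++k) acc += wi[k] * rE[pe[k]];
      }
      const int *pi = preI + (size_t)i * kI;
      double inh = 0.0;
      for (int k = 0; k < kI; ++k) inh += rI[pi[k]];
      const double noise = (!noise_static && noise_sd > 0)
        ? noise_sd * rng.next_norm() : 0.0;
      double drive = p * acc - w_EI * inh + Ibg[i] + noise;
      double v = rE[i] + aE * (drive - rE[i]);
      rEn[i] = v < 0.0 ? 0.0 : (v > r_max ? r_max : v);
    }

    // inhibitory rates
    for (int i = 0; i < NI; ++i) {
      const int *pe = preEI + (size_t)i * kEI;
      double acc = 0.0;
      for (int k = 0; k < kEI; ++k) acc += rE[pe[k]];
      const int *pi = preII + (size_t)i * kII;
      double inh = 0.0;
      for (int k = 0; k < kII; ++k) inh += rI[pi[k]];
      double v = rI[i] + aI * (w_IE * acc - w_II * inh - rI[i]);
      rIn[i] = v < 0.0 ? 0.0 : (v > r_max ? r_max : v);
    }

    rE.swap(rEn);
    rI.swap(rIn);

    // sliding-threshold rate estimates (Euler low-pass of the rates)
    for (int i = 0; i < NE; ++i) rb[i] += aC * (rE[i] - rb[i]);

    // global release factor driven by total weighted inhibitory activity
    double rI_tot = 0.0;
    for (int i = 0; i < NI; ++i) rI_tot += rI[i];
    rI_tot *= w_EI;
    p += aP * (eval_transfer(kind, g, rI_tot) - p);
    p = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);

    if (step % record_every == 0) {
      double m = record(step * dt);
      if (!std::isfinite(m))
        stop("simulate_rate_network: non-finite state at t = %g s", step * dt);
      if (stop_on_runaway) {
        if (m >= 0.95 * r_max) {
          if (runaway_since < 0) runaway_since = step * dt;
          if (step * dt - runaway_since >= 5.0) { runaway = true; break; }
        } else {
          runaway_since = -1.0;
        }
      }
    }
    if (neuron_every > 0 && step % neuron_every == 0) record_neuron(step * dt);
  }

  NumericMatrix W_out(kE, NE);
  std::copy(W.begin(), W.end(), W_out.begin());
  List out = List::create(
    _["trace"] = trace(Range(0, rec_i - 1), _),
    _["r_E"] = NumericVector(rE.begin(), rE.end()),
    _["r_I"] = NumericVector(rI.begin(), rI.end()),
    _["p"] = p,
    _["W_EE"] = W_out,
    _["r_bar"] = NumericVector(rb.begin(), rb.end()),
    _["runaway"] = runaway);
  if (neuron_every > 0) {
    out["rates_E"] = ratesE(Range(0, nrec_i - 1), _);
    out["rates_time"] = rates_time[Range(0, nrec_i - 1)];
  } else {
    out["rates_E"] = R_NilValue;
    out["rates_time"] = R_NilValue;
  }
  return out;
}
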