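#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bernoulli(c) connectivity in compressed sparse row form (by presynaptic
// neuron). Uses the R RNG so the draw is reproducible from set.seed().
// [[Rcpp::export]]
List sample_bernoulli_csr(int n_pre, int n_post, double c, bool exclude_self) {
  std::vector<int> ptr(n_pre + 1, 0);
  std::vector<int> idx;
  idx.reserve((size_t)(n_pre * (double)n_post * c * 1.1) + 64);
  for (int j = 0; j < n_pre; ++j) {
    for (int i = 0; i < n_post; ++i) {
      if (exclude_self && i == j) continue;
      if (unif_rand() < c) idx.push_back(i);
    }
    ptr[j + 1] = (int)idx.size();
  }
  return List::create(_["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
                      _["idx"] = IntegerVector(idx.begin(), idx.end()));
}

// Inverted index for a CSR adjacency: for each postsynaptic neuron, the flat
// edge ids and presynaptic sources that target it.
// [[Rcpp::export]]
List invert_csr(IntegerVector ptr, IntegerVector idx, int n_pre, int n_post) {
  std::vector<int> count(n_post, 0);
  for (int e = 0; e < idx.size(); ++e) count[idx[e]]++;
  std::vector<int> in_ptr(n_post + 1, 0);
  for (int i = 0; i < n_post; ++i) in_ptr[i + 1] = in_ptr[i] + count[i];
  std::vector<int> in_edge(idx.size()), in_pre(idx.size());
  std::vector<int> cursor(in_ptr.begin(), in_ptr.end() - 1);
  for (int j = 0; j < n_pre; ++j) {
    for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
      int i = idx[e];
      in_edge[cursor[i]] = e;
      in_pre[cursor[i]] = j;
      cursor[i]++;
    }
  }
  return List::create(_["ptr"] = IntegerVector(in_ptr.begin(), in_ptr.end()),
                      _["edge"] = IntegerVector(in_edge.begin(), in_edge.end()),
                      _["pre"] = IntegerVector(in_pre.begin(), in_pre.end()));
}

static inline double eval_transfer_sp(int kind, const double *g, double r) {
  switch (kind) {
  case 0: return 1.0;
  case 1: { double v = 1.0 - g[0] * r; return v > 0.0 ? (v < 1.0 ? v : 1.0) : 0.0; }
  case 2: return 1.0 / (1.0 + std::exp(g[1] * (r - g[2])));
  default: return std::exp(-g[3] * r);
  }
}

// Current-based LIF network with per-neuron GABA spillover, neuron-specific
// release factors gating excitatory input onto excitatory cells, and the
// minimal triplet STDP rule with metaplastic LTD on E->E synapses.
//
// Conventions: a spike through weight w increments the target's filtered
// current by w (mean current = w * rate * tau); an inhibitory spike
// additionally increments the target E cell's GABA level by A_GABA / tau_I
// (mean GABA level = afferent inhibitory rate when A_GABA = 1/(c N_I)).
// Neuron ids are global: excitatory 0..N_E-1, inhibitory N_E..N_E+N_I-1.
// [[Rcpp::export]]
List simulate_spiking_cpp(IntegerVector ee_ptr, IntegerVector ee_idx,
                          NumericVector ee_w0,
                          IntegerVector ee_in_ptr, IntegerVector ee_in_edge,
                          IntegerVector ee_in_pre,
                          IntegerVector ei_ptr, IntegerVector ei_idx,
                          IntegerVector ie_ptr, IntegerVector ie_idx,
                          IntegerVector ii_ptr, IntegerVector ii_idx,
                          IntegerVector ext_ptr, IntegerVector ext_idx,
                          int N_E, int N_I, int N_ext, double r_ext,
                          double w_IE, double w_EI, double w_II, double w_ext,
                          double V_R, double V_T, double tau_m, double tau_ref,
                          double tau_E_syn, double tau_I_syn,
                          double A_GABA, double tau_p,
                          int kind, NumericVector g_par,
                          double A_plus, double tau_plus, double tau_slow,
                          double tau_minus, double kappa, double tau_c,
                          double w_max, double rbar_init,
                          double I_const_E, double I_const_I,
                          double duration, double dt,
                          bool plasticity, double warmup,
                          double bin_dt, bool record_spikes,
                          int max_spikes) {
  const int N = N_E + N_I;
  const long n_steps = (long)std::lround(duration / dt);
  const double *g = g_par.begin();

  std::vector<double> V(N, V_R), IE(N, 0.0), II(N, 0.0), Iext(N, 0.0);
  std::vector<int> refr(N, 0);
  std::vector<double> C(N_E, 0.0), p(N_E, kind == 0 ? 1.0 : 1.0);
  std::vector<double> zp(N_E, 0.0), zm(N_E, 0.0), zs(N_E, 0.0);
  std::vector<double> rbar(N_E, rbar_init);
  std::vector<double> W(ee_w0.begin(), ee_w0.end());
  std::vector<double> sum_p(N_E, 0.0), sum_C(N_E, 0.0);
  std::vector<long> spike_count(N, 0);

  const double dE = 1.0 - dt / tau_E_syn;
  const double dI = 1.0 - dt / tau_I_syn;
  const double aP = dt / tau_p;
  const double h = dt / tau_m;
  const double rk4 = 1.0 - h + h * h / 2.0 - h * h * h / 6.0
    + h * h * h * h / 24.0;  // RK4 propagator of the linear membrane ODE
  const int ref_steps = (int)std::lround(tau_ref / dt);
  const double fp = std::exp(-dt / tau_plus);
  const double fm = std::exp(-dt / tau_minus);
  const double fs = std::exp(-dt / tau_slow);
  const double dc = 1.0 - dt / tau_c;
  const double p_ext = r_ext * dt;
  const double Am_coef = A_plus * tau_plus * tau_slow / (tau_minus * kappa);
  const long warm_steps = std::isfinite(warmup)
    ? (long)std::lround(warmup / dt) : n_steps + 1;
  const double gaba_inc = A_GABA / tau_I_syn;

  const long n_bins = (long)std::ceil(n_steps * dt / bin_dt);
  std::vector<double> binE(n_bins, 0.0), binI(n_bins, 0.0);
  const long bin_steps = (long)std::lround(bin_dt / dt);

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  bool spikes_truncated = false;
  std::vector<int> spikers;
  spikers.reserve(256);

  for (long step = 1; step <= n_steps; ++step) {
    const bool plast_on = plasticity && (step - 1) >= warm_steps;
    const double t = step * dt;

    // synaptic current, GABA and release-factor dynamics (forward Euler)
    for (int i = 0; i < N; ++i) {
      IE[i] *= dE; II[i] *= dI; Iext[i] *= dE;
    }
    if (kind != 0) {
      for (int i = 0; i < N_E; ++i) {
        C[i] *= dI;
        p[i] += aP * (eval_transfer_sp(kind, g, C[i]) - p[i]);
      }
    }
    if (plast_on) {
      for (int i = 0; i < N_E; ++i) {
        zp[i] *= fp; zm[i] *= fm; zs[i] *= fs; rbar[i] *= dc;
      }
    }

    // membrane integration (RK4 of the linear ODE; currents held constant
    // within the step) and spike detection
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { refr[i]--; V[i] = V_R; continue; }
      const double Iconst = (i < N_E) ? I_const_E : I_const_I;
      const double S = V_R + IE[i] + II[i] + Iext[i] + Iconst;
      V[i] = S + (V[i] - S) * rk4;
      if (V[i] >= V_T) {
        V[i] = V_R;
        refr[i] = ref_steps;
        spikers.push_back(i);
        spike_count[i]++;
        const long b = (step - 1) / bin_steps;
        if (i < N_E) binE[b] += 1.0; else binI[b] += 1.0;
        if (record_spikes) {
          if ((int)sp_t.size() < max_spikes) {
            sp_t.push_back(t); sp_id.push_back(i);
          } else spikes_truncated = true;
        }
      }
    }

    // external Poisson drive
    for (int j = 0; j < N_ext; ++j) {
      if (unif_rand() < p_ext) {
        for (int e = ext_ptr[j]; e < ext_ptr[j + 1]; ++e)
          Iext[ext_idx[e]] += w_ext;
      }
    }

    // plasticity: LTP on postsynaptic spikes (traces read before their own
    // increments), then LTD on presynaptic spikes, then trace increments
    if (plast_on) {
      for (int s : spikers) {
        if (s >= N_E) continue;
        const double zsl = zs[s];
        for (int q = ee_in_ptr[s]; q < ee_in_ptr[s + 1]; ++q) {
          const int e = ee_in_edge[q];
          if (W[e] <= 0.0 && ee_w0[e] <= 0.0) continue;  // absent synapse
          double w = W[e] + A_plus * zp[ee_in_pre[q]] * zsl;
          W[e] = w > w_max ? w_max : w;
        }
      }
      for (int s : spikers) {
        if (s >= N_E) continue;
        for (int e = ee_ptr[s]; e < ee_ptr[s + 1]; ++e) {
          const int i = ee_idx[e];
          if (W[e] <= 0.0 && ee_w0[e] <= 0.0) continue;
          double w = W[e] - Am_coef * rbar[i] * rbar[i] * zm[i];
          W[e] = w < 0.0 ? 0.0 : w;
        }
      }
      for (int s : spikers) {
        if (s >= N_E) continue;
        zp[s] += 1.0; zm[s] += 1.0; zs[s] += 1.0; rbar[s] += 1.0 / tau_c;
      }
    }

    // spike delivery
    for (int s : spikers) {
      if (s < N_E) {
        for (int e = ee_ptr[s]; e < ee_ptr[s + 1]; ++e) {
          const int i = ee_idx[e];
          IE[i] += p[i] * W[e];  // release gated by the target's p
        }
        for (int e = ei_ptr[s]; e < ei_ptr[s + 1]; ++e)
          IE[N_E + ei_idx[e]] += w_IE;
      } else {
        const int j = s - N_E;
        for (int e = ie_ptr[j]; e < ie_ptr[j + 1]; ++e) {
          const int i = ie_idx[e];
          II[i] += w_EI;          // w_EI < 0
          C[i] += gaba_inc;       // GABA spillover onto E targets
        }
        for (int e = ii_ptr[j]; e < ii_ptr[j + 1]; ++e)
          II[N_E + ii_idx[e]] += w_II;
      }
    }

    for (int i = 0; i < N_E; ++i) { sum_p[i] += p[i]; sum_C[i] += C[i]; }
    if (!std::isfinite(V[0]) || !std::isfinite(IE[0]))
      stop("simulate_spiking: non-finite state at t = %g s", t);
  }

  for (int i = 0; i < N_E; ++i) {
    sum_p[i] /= (double)n_steps;
    sum_C[i] /= (double)n_steps;
  }
  NumericVector rateE(n_bins), rateI(n_bins);
  for (long b = 0; b < n_bins; ++b) {
    const double span = bin_dt;
    rateE[b] = binE[b] / (N_E * span);
    rateI[b] = binI[b] / (N_I * span);
  }
  NumericVector counts(N);
  for (int i = 0; i < N; ++i) counts[i] = (double)spike_count[i];

  return List::create(
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["spikes_truncated"] = spikes_truncated,
    _["rate_E"] = rateE, _["rate_I"] = rateI,
    _["spike_count"] = counts,
    _["V"] = NumericVector(V.begin(), V.end()),
    _["W_EE"] = NumericVector(W.begin(), W.end()),
    _["p"] = NumericVector(p.begin(), p.end()),
    _["C_GABA"] = NumericVector(C.begin(), C.end()),
    _["r_bar"] = NumericVector(rbar.begin(), rbar.end()),
    _["avg_p"] = NumericVector(sum_p.begin(), sum_p.end()),
    _["avg_C"] = NumericVector(sum_C.begin(), sum_C.end()));
}
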