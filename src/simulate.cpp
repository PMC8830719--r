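// Core integrator for the conductance-based E-I integrate-and-fire network.
//
// Dynamics per neuron i of class a in {E, I}:
//   dV/dt = (Vrest - V)/tau_a
//         + (VErev - V) * (g_aO*GO + g_aE*GE)
//         + (VIrev - V) * g_aI*GI
// with GE/GI/GO the exponentially filtered presynaptic spike trains
// (impulse response (1/tau_d) exp(-t/tau_d)).  Subthreshold integration is a
// Heun predictor-corrector step; conductances decay exactly between steps.
// Threshold crossing is checked on the corrected voltage; the spike time is
// the end of the step, the voltage is reset and clamped for the refractory
// period while the conductances keep filtering incoming spikes.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Poisson count by inversion; p0 = exp(-lambda) is precomputed per step
// because lambda is shared across neurons.
static inline int rpois_inv(double lambda, double p0, std::mt19937_64 &rng,
                            std::uniform_real_distribution<double> &unif) {
  double u = unif(rng);
  if (u < p0) return 0;
  int k = 0;
  double p = p0, cdf = p0;
  while (u >= cdf) {
    ++k;
    p *= lambda / k;
    cdf += p;
    if (k > 1000) break; // unreachable for the rates used here
  }
  return k;
}

// [[Rcpp::export]]
List simulate_trial_cpp(IntegerVector adj_offsets,  // length N+1, 0-based into adj_targets
                        IntegerVector adj_targets,  // 0-based target ids
                        int n_exc,
                        List par,                   // model constants (ms, mV)
                        NumericVector rate,         // r_in at step boundaries, length n_steps+1 (1/ms)
                        bool poisson_input,
                        NumericVector v_init,
                        int n_steps,
                        int record_every,           // steps between trace samples
                        bool record_full,
                        int seed) {
  const int N = adj_offsets.size() - 1;
  if (v_init.size() != N) stop("v_init length must equal N");
  const int n_inh = N - n_exc;

  const double dt      = as<double>(par["dt"]);
  const double tau_E   = as<double>(par["tau_E"]);
  const double tau_I   = as<double>(par["tau_I"]);
  const double tau_dE  = as<double>(par["tau_dE"]);
  const double tau_dI  = as<double>(par["tau_dI"]);
  const double V_revE  = as<double>(par["V_revE"]);
  const double V_revI  = as<double>(par["V_revI"]);
  const double V_restE = as<double>(par["V_restE"]);
  const double V_restI = as<double>(par["V_restI"]);
  const double V_th    = as<double>(par["V_th"]);
  const double V_reset = as<double>(par["V_reset"]);
  const double g_EO = as<double>(par["g_EO"]), g_IO = as<double>(par["g_IO"]);
  const double g_EE = as<double>(par["g_EE"]), g_IE = as<double>(par["g_IE"]);
  const double g_EI = as<double>(par["g_EI"]), g_II = as<double>(par["g_II"]);
  const int ref_steps_E = (int)std::lround(as<double>(par["refrac_E"]) / dt);
  const int ref_steps_I = (int)std::lround(as<double>(par["refrac_I"]) / dt);

  const double dec_E = std::exp(-dt / tau_dE);
  const double dec_I = std::exp(-dt / tau_dI);
  const double inc_E = 1.0 / tau_dE;   // filter height of one spike
  const double inc_I = 1.0 / tau_dI;

  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> GE(N, 0.0), GI(N, 0.0), GO(N, 0.0);
  std::vector<int> refr(N, 0);

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  const int n_rec = n_steps / record_every;
  NumericVector lfp_E(n_rec), lfp_I(n_rec);
  NumericMatrix v_full = record_full ? NumericMatrix(n_rec, N) : NumericMatrix(0, 0);

  // time-averaged synaptic currents per population (E-I balance diagnostics)
  double accE_exc = 0.0, accE_inh = 0.0, accI_exc = 0.0, accI_inh = 0.0;
  long n_acc = 0;

  std::vector<int> spikers;
  spikers.reserve(N);

  for (int s = 0; s < n_steps; ++s) {
    const double r_now = rate[s], r_next = rate[s + 1];

    // conductances at t + dt: exact decay plus external arrivals this step
    double lambda = 0.0, p0 = 1.0;
    if (poisson_input && r_now > 0.0) {
      lambda = r_now * dt;
      p0 = std::exp(-lambda);
    }
    double curE_exc = 0.0, curE_inh = 0.0, curI_exc = 0.0, curI_inh = 0.0;

    spikers.clear();
    for (int i = 0; i < N; ++i) {
      const bool exc = i < n_exc;
      const double GE0 = GE[i], GI0 = GI[i];
      double GO0;
      if (poisson_input) {
        GO0 = GO[i];
        double g = GO0 * dec_E;
        if (lambda > 0.0) {
          int k = rpois_inv(lambda, p0, rng, unif);
          if (k > 0) g += k * inc_E;
        }
        GO[i] = g;
      } else {
        GO0 = r_now;
        GO[i] = r_next;
      }
      const double GE1 = GE0 * dec_E, GI1 = GI0 * dec_I;
      GE[i] = GE1;
      GI[i] = GI1;

      const double gO = exc ? g_EO : g_IO;
      const double gE = exc ? g_EE : g_IE;
      const double gI = exc ? g_EI : g_II;
      const double tau = exc ? tau_E : tau_I;
      const double vrest = exc ? V_restE : V_restI;

      const double v = V[i];
      // diagnostics use the state at the start of the step
      {
        const double iexc = (V_revE - v) * (gO * GO0 + gE * GE0);
        const double iinh = (V_revI - v) * (gI * GI0);
        if (exc) { curE_exc += iexc; curE_inh += iinh; }
        else     { curI_exc += iexc; curI_inh += iinh; }
      }

      if (refr[i] > 0) {
        --refr[i];
        V[i] = V_reset;
        continue;
      }

      const double f1 = (vrest - v) / tau + (V_revE - v) * (gO * GO0 + gE * GE0)
                        + (V_revI - v) * (gI * GI0);
      const double vp = v + dt * f1;
      const double f2 = (vrest - vp) / tau + (V_revE - vp) * (gO * GO[i] + gE * GE1)
                        + (V_revI - vp) * (gI * GI1);
      double vn = v + 0.5 * dt * (f1 + f2);

      if (vn >= V_th) {
        spike_id.push_back(i);
        spike_t.push_back((s + 1) * dt);
        vn = V_reset;
        refr[i] = exc ? ref_steps_E : ref_steps_I;
        spikers.push_back(i);
      }
      V[i] = vn;
    }

    accE_exc += curE_exc / n_exc;
    accE_inh += curE_inh / n_exc;
    if (n_inh > 0) {
      accI_exc += curI_exc / n_inh;
      accI_inh += curI_inh / n_inh;
    }
    ++n_acc;

    // deliver this step's spikes; they act on targets from the next step on
    for (int j : spikers) {
      const bool exc = j < n_exc;
      const double inc = exc ? inc_E : inc_I;
      const int from = adj_offsets[j], to = adj_offsets[j + 1];
      if (exc) {
        for (int e = from; e < to; ++e) GE[adj_targets[e]] += inc;
      } else {
        for (int e = from; e < to; ++e) GI[adj_targets[e]] += inc;
      }
    }

    if ((s + 1) % record_every == 0) {
      const int r = (s + 1) / record_every - 1;
      double mE = 0.0, mI = 0.0;
      for (int i = 0; i < n_exc; ++i) mE += V[i];
      for (int i = n_exc; i < N; ++i) mI += V[i];
      mE /= n_exc;
      mI = (n_inh > 0) ? mI / n_inh : NA_REAL;
      if (!std::isfinite(mE)) stop("numerical divergence at step %d", s + 1);
      lfp_E[r] = mE;
      lfp_I[r] = mI;
      if (record_full) for (int i = 0; i < N; ++i) v_full(r, i) = V[i];
    }
  }

  return List::create(
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_t"]  = NumericVector(spike_t.begin(), spike_t.end()),
    _["lfp_E"]    = lfp_E,
    _["lfp_I"]    = lfp_I,
    _["v_full"]   = v_full,
    _["currents"] = NumericVector::create(
      _["E_exc"] = accE_exc / n_acc, _["E_inh"] = accE_inh / n_acc,
      _["I_exc"] = accI_exc / n_acc, _["I_inh"] = accI_inh / n_acc));
}

// Random directed graph: edge j -> k present independently with probability p,
// no self loops.  Returns CSR offsets/targets (0-based).
// [[Rcpp::export]]
List build_topology_cpp(int N, double p, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::geometric_distribution<int> geom(p < 1.0 ? p : 0.5);

  std::vector<int> offsets(N + 1, 0);
  std::vector<int> targets;
  targets.reserve((size_t)(p * N * (double)N * 1.05) + 64);

  for (int j = 0; j < N; ++j) {
    if (p >= 1.0) {
      for (int k = 0; k < N; ++k) if (k != j) targets.push_back(k);
    } else if (p > 0.0) {
      // geometric skipping over the Bernoulli sequence
      int k = geom(rng);
      while (k < N) {
        if (k != j) targets.push_back(k);
        k += 1 + geom(rng);
      }
    }
    offsets[j + 1] = (int)targets.size();
  }
  return List::create(_["offsets"] = IntegerVector(offsets.begin(), offsets.end()),
                      _["targets"] = IntegerVector(targets.begin(), targets.end()));
}
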