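#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire encoder for a sampled current waveform.
// Membrane convention: dv/dt = (I - v) / tau, so the steady state for a
// constant current I is v = I and the closed-form inter-spike interval for
// I > v_thr is tau * log(I / (I - v_thr)).
// Integration is exact per sample step for piecewise-constant input:
//   v <- v * a + I * (1 - a),  a = exp(-dt / tau).
// [[Rcpp::export]]
NumericVector lif_encode_cpp(NumericVector current, double fs, double tau,
                             double v_thr, double v_reset, double refractory,
                             double v0) {
  const int n = current.size();
  const double dt = 1.0 / fs;
  const double a = std::exp(-dt / tau);
  std::vector<double> spikes;
  double v = v0;
  double t_ok = 0.0; // end of refractory period
  for (int i = 0; i < n; ++i) {
    double t = (i + 1) * dt; // state at end of step i
    if (t > t_ok) {
      v = v * a + current[i] * (1.0 - a);
      if (v >= v_thr) {
        spikes.push_back(t);
        v = v_reset;
        t_ok = t + refractory;
      }
    }
  }
  return wrap(spikes);
}

// Clock-driven simulator for recurrently connected LIF populations with
// exponentially decaying synaptic currents.
//
// Neurons: dv/dt = (I_tot - v) / tau_m, spike at v >= v_thr, reset to
// v_reset, absolute refractory period. I_tot is the sum of per-time-constant
// synaptic accumulators; a presynaptic event on an edge with weight w and
// time-constant index k adds w to accumulator k of the postsynaptic neuron,
// and each accumulator decays as exp(-dt/tau_syn[k]).
//
// Recurrent wiring is CSR over presynaptic neurons (adj_ptr has n+1 entries).
// External sources are virtual presynaptic units: ext_time/ext_src give their
// (sorted) spike times, ext_ptr/ext_post/ext_w/ext_k their outgoing edges.
//
// Returns a list with spike times/ids, or aborts with ok = false when the
// population-mean rate exceeds rate_cap (runaway excitation guard).
// [[Rcpp::export]]
List simulate_net_cpp(NumericVector tau_m, NumericVector v_thr,
                      NumericVector v_reset, NumericVector refractory,
                      IntegerVector adj_ptr, IntegerVector adj_post,
                      NumericVector adj_w, IntegerVector adj_k,
                      NumericVector syn_tau,
                      NumericVector ext_time, IntegerVector ext_src,
                      IntegerVector ext_ptr, IntegerVector ext_post,
                      NumericVector ext_w, IntegerVector ext_k,
                      double duration, double dt, double rate_cap) {
  const int n = tau_m.size();
  const int nk = syn_tau.size();
  const int nsteps = (int)std::ceil(duration / dt);
  std::vector<double> decay_m(n), syn_decay(nk);
  for (int i = 0; i < n; ++i) decay_m[i] = std::exp(-dt / tau_m[i]);
  for (int k = 0; k < nk; ++k) syn_decay[k] = std::exp(-dt / syn_tau[k]);

  std::vector<double> v(n, 0.0), t_ok(n, 0.0);
  std::vector<double> I(n * (size_t)nk, 0.0); // column-major: I[k*n + i]
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  const size_t cap = rate_cap > 0
    ? (size_t)std::ceil(rate_cap * n * duration) + 16 : (size_t)-1;

  int ext_i = 0;
  const int n_ext = ext_time.size();

  for (int s = 0; s < nsteps; ++s) {
    const double t = (s + 1) * dt;
    // deliver external events that fall inside this step
    while (ext_i < n_ext && ext_time[ext_i] < t) {
      const int src = ext_src[ext_i];
      for (int e = ext_ptr[src]; e < ext_ptr[src + 1]; ++e)
        I[(size_t)ext_k[e] * n + ext_post[e]] += ext_w[e];
      ++ext_i;
    }
    // decay synaptic currents
    for (int k = 0; k < nk; ++k) {
      double d = syn_decay[k];
      double *col = &I[(size_t)k * n];
      for (int i = 0; i < n; ++i) col[i] *= d;
    }
    // membrane update and threshold crossing
    for (int i = 0; i < n; ++i) {
      if (t <= t_ok[i]) continue;
      double itot = 0.0;
      for (int k = 0; k < nk; ++k) itot += I[(size_t)k * n + i];
      v[i] = v[i] * decay_m[i] + itot * (1.0 - decay_m[i]);
      if (v[i] >= v_thr[i]) {
        sp_t.push_back(t);
        sp_id.push_back(i + 1); // 1-based neuron ids for R
        v[i] = v_reset[i];
        t_ok[i] = t + refractory[i];
        for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e)
          I[(size_t)adj_k[e] * n + adj_post[e]] += adj_w[e];
        if (sp_t.size() > cap)
          return List::create(_["ok"] = false, _["time"] = R_NilValue,
                              _["neuron"] = R_NilValue);
      }
    }
  }
  return List::create(_["ok"] = true, _["time"] = wrap(sp_t),
                      _["neuron"] = wrap(sp_id));
}
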