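// Fixed-step exponential-Euler integrator for a conductance-based leaky
// integrate-and-fire network with exponential-decay synapses, piecewise-
// constant Poisson spike drives and piecewise-constant current drives.
//
// Units: time ms, voltage mV, capacitance nF, current nA, conductance nS.
// Synaptic current (nA) = g (nS) * (E_rev - V) (mV) / 1000.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Segment {
  int neuron;
  int receptor;   // -1 for current segments
  double t_on, t_off;
  double rate_hz; // Poisson rate (ignored for currents)
  double g_inc;   // conductance increment per spike (nS)
  double i_na;    // current (nA)
};

// [[Rcpp::export(name = ".lif_run")]]
List lif_run(int n_neurons,
             NumericVector tau_m, NumericVector v_rest,
             NumericVector v_thr, NumericVector v_reset,
             NumericVector t_ref, NumericVector c_m,
             NumericVector rec_tau, NumericVector rec_erev,
             NumericVector rec_alpha,
             IntegerVector syn_pre, IntegerVector syn_post,
             IntegerVector syn_rec, NumericVector syn_g,
             NumericMatrix poisson_seg,  // cols: neuron, receptor, on, off, rate, g_inc
             NumericMatrix current_seg,  // cols: neuron, on, off, i_na
             double duration_ms, double dt_ms, int seed,
             NumericVector v_init,
             IntegerVector record_v_ids, int record_stride) {
  const int n_rec = rec_tau.size();
  const int n_steps = (int)std::llround(duration_ms / dt_ms);
  if (n_steps <= 0) stop("duration must be a positive multiple of dt");

  // receptor decay factors
  std::vector<double> decay(n_rec);
  for (int r = 0; r < n_rec; ++r) decay[r] = std::exp(-dt_ms / rec_tau[r]);

  // per-synapse saturating gating variable s in [0, 1]: on each presynaptic
  // spike s += alpha * (1 - s) and the postsynaptic conductance rises by
  // g_max * ds, so a synapse's conductance contribution never exceeds g_max
  // (receptors with alpha <= 0 use plain linear increments)
  const int n_syn_total = syn_pre.size();
  std::vector<double> syn_s(n_syn_total, 0.0);
  std::vector<double> syn_last(n_syn_total, -1e18);

  // adjacency in CSR form
  const int n_syn = syn_pre.size();
  std::vector<int> out_count(n_neurons, 0);
  for (int s = 0; s < n_syn; ++s) out_count[syn_pre[s]]++;
  std::vector<int> row_ptr(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) row_ptr[i + 1] = row_ptr[i] + out_count[i];
  std::vector<int> adj_post(n_syn), adj_rec(n_syn), adj_syn(n_syn);
  std::vector<double> adj_g(n_syn);
  {
    std::vector<int> fill(row_ptr.begin(), row_ptr.end() - 1);
    for (int s = 0; s < n_syn; ++s) {
      int p = fill[syn_pre[s]]++;
      adj_post[p] = syn_post[s];
      adj_rec[p] = syn_rec[s];
      adj_g[p] = syn_g[s];
      adj_syn[p] = s;
    }
  }

  // assemble segments, sorted by onset
  std::vector<Segment> segs;
  for (int i = 0; i < poisson_seg.nrow(); ++i) {
    Segment s;
    s.neuron = (int)poisson_seg(i, 0);
    s.receptor = (int)poisson_seg(i, 1);
    s.t_on = poisson_seg(i, 2); s.t_off = poisson_seg(i, 3);
    s.rate_hz = poisson_seg(i, 4); s.g_inc = poisson_seg(i, 5);
    s.i_na = 0.0;
    if (s.neuron < 0 || s.neuron >= n_neurons) stop("poisson segment: bad neuron id");
    if (s.receptor < 0 || s.receptor >= n_rec) stop("poisson segment: bad receptor");
    if (s.rate_hz < 0) stop("poisson segment: negative rate");
    segs.push_back(s);
  }
  for (int i = 0; i < current_seg.nrow(); ++i) {
    Segment s;
    s.neuron = (int)current_seg(i, 0);
    s.receptor = -1;
    s.t_on = current_seg(i, 1); s.t_off = current_seg(i, 2);
    s.rate_hz = 0.0; s.g_inc = 0.0;
    s.i_na = current_seg(i, 3);
    if (s.neuron < 0 || s.neuron >= n_neurons) stop("current segment: bad neuron id");
    segs.push_back(s);
  }
  std::stable_sort(segs.begin(), segs.end(),
                   [](const Segment& a, const Segment& b) { return a.t_on < b.t_on; });

  // state
  std::vector<double> V(n_neurons);
  for (int i = 0; i < n_neurons; ++i)
    V[i] = (v_init.size() == n_neurons) ? v_init[i] : v_rest[i];
  std::vector<double> g(n_neurons * n_rec, 0.0);
  std::vector<double> ref_until(n_neurons, -1.0);
  std::vector<double> i_ext(n_neurons, 0.0);

  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 1442695040888963407ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  // membrane recording
  const int n_recv = record_v_ids.size();
  int n_samples = (n_recv > 0 && record_stride > 0)
    ? (n_steps / record_stride) : 0;
  NumericMatrix v_out(n_samples, n_recv);
  int sample_row = 0;

  // active Poisson segments (indices into segs)
  std::vector<int> active;
  size_t next_seg = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt_ms;
    // activate segments starting at or before t
    while (next_seg < segs.size() && segs[next_seg].t_on <= t + 1e-9) {
      const Segment& s = segs[next_seg];
      if (s.t_off > t + 1e-9) {
        if (s.receptor < 0) i_ext[s.neuron] += s.i_na;
        active.push_back((int)next_seg);
      }
      ++next_seg;
    }
    // expire segments
    for (size_t k = 0; k < active.size();) {
      const Segment& s = segs[active[k]];
      if (s.t_off <= t + 1e-9) {
        if (s.receptor < 0) i_ext[s.neuron] -= s.i_na;
        active[k] = active.back();
        active.pop_back();
      } else ++k;
    }
    // Poisson arrivals
    for (size_t k = 0; k < active.size(); ++k) {
      const Segment& s = segs[active[k]];
      if (s.receptor >= 0) {
        double p = s.rate_hz * dt_ms * 1e-3;
        if (p > 0 && unif(rng) < p)
          g[s.neuron * n_rec + s.receptor] += s.g_inc;
      }
    }
    // integrate neurons
    for (int i = 0; i < n_neurons; ++i) {
      double* gi = &g[i * n_rec];
      double gsum = 0.0, gesum = 0.0;
      for (int r = 0; r < n_rec; ++r) {
        gsum += gi[r];
        gesum += gi[r] * rec_erev[r];
        gi[r] *= decay[r];
      }
      if (t < ref_until[i]) { V[i] = v_reset[i]; continue; }
      const double a = 1.0 / tau_m[i] + gsum / (1000.0 * c_m[i]);
      const double b = v_rest[i] / tau_m[i] +
        gesum / (1000.0 * c_m[i]) + i_ext[i] / c_m[i];
      const double v_inf = b / a;
      V[i] = v_inf + (V[i] - v_inf) * std::exp(-a * dt_ms);
      if (!std::isfinite(V[i]))
        stop("integration instability: non-finite potential at t = %.3f ms, neuron %d",
             t, i);
      if (V[i] >= v_thr[i]) {
        spike_id.push_back(i);
        spike_t.push_back(t + dt_ms);
        V[i] = v_reset[i];
        ref_until[i] = t + dt_ms + t_ref[i];
        for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) {
          const int r = adj_rec[p];
          const double alpha = rec_alpha[r];
          if (alpha > 0.0) {
            const int k = adj_syn[p];
            double s = syn_s[k] *
              std::exp(-(t - syn_last[k]) / rec_tau[r]);
            const double ds = alpha * (1.0 - s);
            g[adj_post[p] * n_rec + r] += adj_g[p] * ds;
            syn_s[k] = s + ds;
            syn_last[k] = t;
          } else {
            g[adj_post[p] * n_rec + r] += adj_g[p];
          }
        }
      }
    }
    if (n_samples > 0 && (step + 1) % record_stride == 0 && sample_row < n_samples) {
      for (int k = 0; k < n_recv; ++k)
        v_out(sample_row, k) = V[record_v_ids[k]];
      ++sample_row;
    }
  }

  return List::create(_["neuron_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
                      _["time_ms"] = NumericVector(spike_t.begin(), spike_t.end()),
                      _["v"] = v_out);
}
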