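// Event-driven simulation of the visual-cortex local network:
// C1 input cells (latency-coded stimulus spikes + Poisson spontaneous
// activity) project through plastic synapses onto a small population of
// leaky integrate-and-fire S2 cells with sinusoidal (alpha-like) input-gain
// modulation, first-spike winner-take-all competition, and classical STDP.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_local_run(IntegerVector plan_cell,   // 0-based C1 ids per spike
                   NumericVector plan_time,   // ms within presentation
                   IntegerVector plan_offset, // length n_pres+1
                   int n_c1, int n_s2,
                   NumericVector w0, double w_max,
                   double dA_pre, double dA_post,
                   double tau_pre, double tau_post,
                   double tau_m, double v_thresh, double refractory_ms,
                   double input_gain,
                   double alpha_m, double alpha_period, double alpha_phase,
                   double stim_ms, double relax_ms,
                   double rate_hz,
                   bool plastic, bool wta, bool one_spike,
                   int snapshot_every,
                   bool record_s2) {
  const int n_pres = plan_offset.size() - 1;
  const double period = stim_ms + relax_ms;
  std::vector<double> w(w0.begin(), w0.end()); // w[j + n_c1*i], j pre, i post
  // presynaptic traces in scaled form, rebased at each presentation start:
  // A_pre[j](t) = B_pre[j] * exp(-(t - T0) / tau_pre)
  std::vector<double> B_pre(n_c1, 0.0);
  std::vector<double> A_post(n_s2, 0.0), t_Apost(n_s2, 0.0);
  std::vector<double> v(n_s2, 0.0);
  std::vector<double> last_spike(n_s2, -1e18);
  std::vector<char> inhibited(n_s2, 0);

  IntegerVector winner(n_pres, -1);
  NumericVector first_latency(n_pres, NA_REAL);
  IntegerMatrix s2_counts(n_pres, n_s2);

  std::vector<double> s2_t;
  std::vector<int> s2_cell;
  std::vector<int> s2_off(1, 0);

  int n_snap = (snapshot_every > 0) ? n_pres / snapshot_every : 0;
  NumericMatrix snapshots(n_snap, plastic ? (int)w.size() : 0);
  IntegerVector snap_pres(n_snap);
  int snap_i = 0;

  const double bg_total = rate_hz * n_c1; // population background rate, Hz

  const double pres_decay_pre = std::exp(-period / tau_pre);
  for (int p = 0; p < n_pres; ++p) {
    const double T0 = p * period;
    // presentation-local reset: relaxation brings potentials back to rest
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(inhibited.begin(), inhibited.end(), 0);
    double t_v = T0; // time potentials were last decayed to
    if (plastic && p > 0) { // rebase scaled pre traces to the new T0
      for (int j = 0; j < n_c1; ++j) B_pre[j] *= pres_decay_pre;
    }

    int ip = plan_offset[p];           // stimulus spike pointer
    const int ip_end = plan_offset[p + 1];
    double bg_next = (bg_total > 0.0)
      ? T0 + R::rexp(1000.0 / bg_total) : 1e18;

    while (true) {
      double t_stim = (ip < ip_end) ? T0 + plan_time[ip] : 1e18;
      double t_ev = std::min(t_stim, bg_next);
      if (t_ev > T0 + period) break;
      int cell;
      if (t_stim <= bg_next) {
        cell = plan_cell[ip]; ++ip;
      } else {
        cell = (int)std::floor(unif_rand() * n_c1);
        if (cell >= n_c1) cell = n_c1 - 1;
        bg_next += R::rexp(1000.0 / bg_total);
      }
      // decay membrane potentials to t_ev
      double decv = std::exp(-(t_ev - t_v) / tau_m);
      for (int i = 0; i < n_s2; ++i) v[i] *= decv;
      t_v = t_ev;
      double gain = 1.0 + alpha_m *
        std::sin(2.0 * M_PI * t_ev / alpha_period + alpha_phase);
      if (gain < 0.0) gain = 0.0;
      // STDP: presynaptic event
      if (plastic) {
        for (int i = 0; i < n_s2; ++i) {
          A_post[i] *= std::exp(-(t_ev - t_Apost[i]) / tau_post);
          t_Apost[i] = t_ev;
          double nw = w[cell + (size_t)n_c1 * i] + A_post[i];
          w[cell + (size_t)n_c1 * i] = nw < 0.0 ? 0.0 : (nw > w_max ? w_max : nw);
        }
        B_pre[cell] += dA_pre * std::exp((t_ev - T0) / tau_pre);
      }
      // synaptic transmission
      for (int i = 0; i < n_s2; ++i) {
        if (inhibited[i]) continue;
        if (t_ev - last_spike[i] <= refractory_ms) continue;
        v[i] += w[cell + (size_t)n_c1 * i] * gain * input_gain;
      }
      // threshold crossings
      for (int i = 0; i < n_s2; ++i) {
        if (inhibited[i] || v[i] < v_thresh) continue;
        if (t_ev - last_spike[i] <= refractory_ms) continue;
        v[i] = 0.0;
        last_spike[i] = t_ev;
        s2_counts(p, i) += 1;
        if (record_s2) { s2_t.push_back(t_ev - T0); s2_cell.push_back(i); }
        if (winner[p] < 0) {
          winner[p] = i;
          first_latency[p] = t_ev - T0;
          if (wta) { // first spike silences competitors for the presentation
            for (int q = 0; q < n_s2; ++q) if (q != i) inhibited[q] = 1;
          }
        }
        if (one_spike) inhibited[i] = 1; // single spike per presentation
        if (plastic) { // postsynaptic STDP event: potentiate by pre traces
          A_post[i] *= std::exp(-(t_ev - t_Apost[i]) / tau_post);
          t_Apost[i] = t_ev;
          const double pre_fac = std::exp(-(t_ev - T0) / tau_pre);
          double *wi = &w[(size_t)n_c1 * i];
          for (int j = 0; j < n_c1; ++j) {
            double nw = wi[j] + B_pre[j] * pre_fac;
            wi[j] = nw < 0.0 ? 0.0 : (nw > w_max ? w_max : nw);
          }
          A_post[i] += dA_post;
        }
      }
    }
    if (record_s2) s2_off.push_back((int)s2_t.size());
    if (snapshot_every > 0 && (p + 1) % snapshot_every == 0 &&
        snap_i < n_snap && plastic) {
      for (size_t q = 0; q < w.size(); ++q) snapshots(snap_i, q) = w[q];
      snap_pres[snap_i] = p + 1;
      ++snap_i;
    }
    if ((p & 63) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["winner"] = winner,
    _["first_latency"] = first_latency,
    _["s2_counts"] = s2_counts,
    _["snapshots"] = snapshots,
    _["snap_pres"] = snap_pres);
  if (record_s2) {
    out["s2_t"] = NumericVector(s2_t.begin(), s2_t.end());
    out["s2_cell"] = IntegerVector(s2_cell.begin(), s2_cell.end());
    out["s2_offset"] = IntegerVector(s2_off.begin(), s2_off.end());
  }
  return out;
}
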