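// Clock-driven simulation of the full network: a global neuronal workspace
// (GNW) of excitatory LIF neurons split into digit-selective groups plus an
// optional interneuron population, a single motor-cortex neuron, and a single
// striatal dopamine neuron gating reward delivery. Internal excitatory
// synapses follow classical STDP, synapses with an interneuron endpoint
// follow symmetric (GABAergic) STDP, and GNW-to-motor synapses follow
// dopamine-modulated STDP with eligibility traces.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gnw_run(int n_exc, int n_inh,
                 IntegerVector group,        // length n_exc, values 0/1
                 NumericMatrix W,            // N x N magnitudes, W(i,j): i -> j
                 NumericVector w_mc0,        // n_exc
                 double w_max_ee, double w_max_ei, double w_max_ie,
                 double w_mc_max,
                 NumericVector vc_w, // per-excitatory-neuron input weight
                 IntegerVector trial_label,
                 IntegerVector trial_group,  // -1: no front-end responder
                 NumericVector in_t, IntegerVector in_offset,
                 double stim_ms, double gap_ms, double trigger_ms,
                 double resp_extra_ms, double trial_ms,
                 double trigger_amp,
                 double tau_m, double v_thresh, double refractory_ms,
                 double dt,
                 double rate_hz, double kick,
                 double ee_dA_pre, double ee_dA_post,
                 double ee_tau_pre, double ee_tau_post,
                 double sy_dA_pre, double sy_dA_post,
                 double sy_tau_pre, double sy_tau_post, double sy_div,
                 double da_dA_pre, double da_dA_post,
                 double da_tau_pre, double da_tau_post,
                 double tau_c, double tau_d, double tau_s,
                 double reward_magnitude, double da_jitter_ms,
                 int mc_threshold, double decision_x, double mc_syn_tau,
                 double tau_syn_e, double tau_syn_i, double tau_syn_vc,
                 bool plastic_internal, bool plastic_da,
                 int snapshot_every,
                 bool record_raster, int raster_max) {
  const int N = n_exc + n_inh;
  const int n_trials = trial_label.size();
  const double trig_on = stim_ms + gap_ms;
  const double trig_off = trig_on + trigger_ms;
  const double resp_end = trig_off + resp_extra_ms;
  const int steps = (int)std::lround(trial_ms / dt);

  std::vector<double> v(N, 0.0), last(N, -1e18);
  // recurrent transmission uses exponential synaptic currents: slow
  // excitation and faster inhibition, the standard substrate for stable
  // asynchronous persistent activity in attractor networks
  std::vector<double> Ie(N, 0.0), Ii(N, 0.0);
  std::vector<double> Iv(n_exc, 0.0); // sensory (VC) current, fast decay
  const double dec_se = std::exp(-dt / tau_syn_e);
  const double dec_si = std::exp(-dt / tau_syn_i);
  const double dec_sv = std::exp(-dt / tau_syn_vc);
  // motor cortex: exponential-current synapse (input current I_mc with time
  // constant mc_syn_tau) so its firing rate grades with workspace drive
  double v_mc = 0.0, last_mc = -1e18, I_mc = 0.0;
  const double dec_syn = std::exp(-dt / mc_syn_tau);
  std::vector<double> w_mc(w_mc0.begin(), w_mc0.end());
  NumericMatrix Wl = clone(W);

  // classical traces (excitatory-excitatory)
  std::vector<double> Ae_pre(n_exc, 0.0), te_pre(n_exc, 0.0);
  std::vector<double> Ae_post(n_exc, 0.0), te_post(n_exc, 0.0);
  // symmetric traces (any neuron, used for interneuron-endpoint synapses)
  const double rest_pre = -sy_dA_pre / sy_div;
  const double rest_post = -sy_dA_post / sy_div;
  std::vector<double> As_pre(N, rest_pre), ts_pre(N, 0.0);
  std::vector<double> As_post(N, rest_post), ts_post(N, 0.0);
  // dopamine pathway
  std::vector<double> Am_pre(n_exc, 0.0), tm_pre(n_exc, 0.0);
  double Am_post = 0.0, tm_post = 0.0;
  std::vector<double> c(n_exc, 0.0), s(n_exc, 0.0);
  double d = 0.0, pending_reward = 0.0;

  const double dec_m = std::exp(-dt / tau_m);
  const double dec_c = std::exp(-dt / tau_c);
  const double dec_d = std::exp(-dt / tau_d);
  const double dec_s = std::exp(-dt / tau_s);

  // background for GNW neurons and the motor neuron (index N)
  std::vector<double> next_bg(N + 1, 1e18);
  if (rate_hz > 0)
    for (int i = 0; i <= N; ++i) next_bg[i] = R::rexp(1000.0 / rate_hz);

  IntegerVector out_pressed(n_trials), out_correct(n_trials),
      out_reward(n_trials), out_mc(n_trials);
  NumericVector out_lat(n_trials, NA_REAL);
  // per-trial group spike counts in stimulus / gap / trigger windows
  NumericMatrix win_counts(n_trials, 9);
  // diagnostics: reward delivered, mean eligibility per group at delivery
  NumericMatrix diag(n_trials, 3);

  int n_snap = snapshot_every > 0 ? n_trials / snapshot_every : 0;
  NumericMatrix mc_snap(n_snap, n_exc);
  NumericMatrix ee_snap(n_snap, 5); // g0-g0, g1-g1, cross, exc->inh, inh->exc
  IntegerVector snap_trial(n_snap);
  int snap_i = 0;

  std::vector<int> ras_n; std::vector<double> ras_t;

  std::vector<int> spiking; spiking.reserve(N);

  for (int tr = 0; tr < n_trials; ++tr) {
    const double T0 = tr * trial_ms;
    // the relaxation tail of each trial returns membrane potentials and
    // synaptic currents to rest before the next image
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(Ie.begin(), Ie.end(), 0.0);
    std::fill(Ii.begin(), Ii.end(), 0.0);
    std::fill(Iv.begin(), Iv.end(), 0.0);
    v_mc = 0.0; I_mc = 0.0;
    const int g_in = trial_group[tr];
    int ip = in_offset[tr], ip_end = in_offset[tr + 1];
    double stri_t = da_jitter_ms > 0 ? unif_rand() * da_jitter_ms : 0.0;
    bool stri_done = false;
    int mc_count = 0;
    double first_lat = NA_REAL;

    for (int st = 0; st < steps; ++st) {
      const double t_rel = (st + 1) * dt;
      const double t = T0 + t_rel;
      const bool in_trigger = t_rel > trig_on && t_rel <= trig_off;
      const bool in_resp = t_rel > trig_on && t_rel <= resp_end;

      // striatum fires once per image shortly after onset; gates reward
      if (!stri_done && t_rel >= stri_t) {
        stri_done = true;
        if (plastic_da && pending_reward != 0.0) {
          d += pending_reward;
          diag(tr, 0) = pending_reward;
          double c0 = 0, c1 = 0; int n0 = 0, n1 = 0;
          for (int j = 0; j < n_exc; ++j) {
            double cj = c[j] * std::exp(-(t - tm_pre[j]) / tau_c);
            if (group[j] == 0) { c0 += cj; ++n0; } else { c1 += cj; ++n1; }
          }
          diag(tr, 1) = n0 ? c0 / n0 : 0;
          diag(tr, 2) = n1 ? c1 / n1 : 0;
          pending_reward = 0.0;
        }
        if (record_raster && (int)ras_n.size() < raster_max) {
          ras_n.push_back(N + 1); ras_t.push_back(t);
        }
      }

      // membrane relaxes toward the net synaptic current (+ trigger drive)
      for (int i = 0; i < N; ++i) {
        double target = Ie[i] - Ii[i];
        if (i < n_exc) {
          target += Iv[i];
          Iv[i] *= dec_sv;
          if (in_trigger) target += trigger_amp;
        }
        v[i] = target + (v[i] - target) * dec_m;
        Ie[i] *= dec_se;
        Ii[i] *= dec_si;
      }
      v_mc = I_mc + (v_mc - I_mc) * dec_m;
      I_mc *= dec_syn;

      // spontaneous background kicks (per-neuron Poisson)
      if (rate_hz > 0) {
        for (int i = 0; i < N; ++i) {
          while (next_bg[i] <= t) {
            if (t - last[i] > refractory_ms) v[i] += kick;
            next_bg[i] += R::rexp(1000.0 / rate_hz);
          }
        }
        while (next_bg[N] <= t) {
          I_mc += kick;
          next_bg[N] += R::rexp(1000.0 / rate_hz);
        }
      }

      // front-end (S2) input spikes drive the matching selective group
      while (ip < ip_end && in_t[ip] <= t_rel) {
        if (g_in >= 0) {
          for (int i = 0; i < n_exc; ++i)
            if (group[i] == g_in) Iv[i] += vc_w[i];
        }
        ++ip;
      }

      // threshold crossings
      spiking.clear();
      for (int i = 0; i < N; ++i) {
        if (t - last[i] <= refractory_ms) { v[i] = 0.0; continue; }
        if (v[i] >= v_thresh) {
          v[i] = 0.0; last[i] = t;
          spiking.push_back(i);
        }
      }

      for (size_t q = 0; q < spiking.size(); ++q) {
        const int i = spiking[q];
        const bool i_exc = i < n_exc;
        if (record_raster && (int)ras_n.size() < raster_max) {
          ras_n.push_back(i); ras_t.push_back(t);
        }
        // window bookkeeping
        int pop = i_exc ? group[i] : 2;
        if (t_rel > trig_on && t_rel <= trig_off) win_counts(tr, 6 + pop) += 1;
        else if (t_rel <= stim_ms) win_counts(tr, pop) += 1;
        else if (t_rel <= trig_on) win_counts(tr, 3 + pop) += 1;
        // synaptic transmission (exponential currents)
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          double wij = Wl(i, j);
          if (wij != 0.0) {
            if (i_exc) Ie[j] += wij; else Ii[j] += wij;
          }
        }
        if (i_exc) I_mc += w_mc[i];

        if (i_exc && plastic_da) {
          // dopamine eligibility: i as presynaptic to MC
          Am_post *= std::exp(-(t - tm_post) / da_tau_post);
          tm_post = t;
          c[i] = c[i] * std::exp(-(t - tm_pre[i]) / tau_c) + Am_post;
          Am_pre[i] = Am_pre[i] * std::exp(-(t - tm_pre[i]) / da_tau_pre)
            + da_dA_pre;
          tm_pre[i] = t;
        }
        if (!plastic_internal) continue;
        if (i_exc) {
          // classical STDP with excitatory partners
          Ae_pre[i] = Ae_pre[i] * std::exp(-(t - te_pre[i]) / ee_tau_pre);
          te_pre[i] = t;
          Ae_post[i] = Ae_post[i] * std::exp(-(t - te_post[i]) / ee_tau_post);
          te_post[i] = t;
          for (int j = 0; j < n_exc; ++j) {
            if (j == i) continue;
            Ae_post[j] *= std::exp(-(t - te_post[j]) / ee_tau_post);
            te_post[j] = t;
            Ae_pre[j] *= std::exp(-(t - te_pre[j]) / ee_tau_pre);
            te_pre[j] = t;
            double nw = Wl(i, j) + Ae_post[j]; // i as presynaptic: depression
            Wl(i, j) = nw < 0 ? 0 : (nw > w_max_ee ? w_max_ee : nw);
            nw = Wl(j, i) + Ae_pre[j];         // i as postsynaptic: potentiation
            Wl(j, i) = nw < 0 ? 0 : (nw > w_max_ee ? w_max_ee : nw);
          }
          Ae_pre[i] += ee_dA_pre;
          Ae_post[i] += ee_dA_post;
          // symmetric STDP with interneuron partners
          for (int j = n_exc; j < N; ++j) {
            As_post[j] = rest_post +
              (As_post[j] - rest_post) * std::exp(-(t - ts_post[j]) / sy_tau_post);
            ts_post[j] = t;
            As_pre[j] = rest_pre +
              (As_pre[j] - rest_pre) * std::exp(-(t - ts_pre[j]) / sy_tau_pre);
            ts_pre[j] = t;
            double nw = Wl(i, j) + As_post[j];
            Wl(i, j) = nw < 0 ? 0 : (nw > w_max_ei ? w_max_ei : nw);
            nw = Wl(j, i) + As_pre[j];
            Wl(j, i) = nw < 0 ? 0 : (nw > w_max_ie ? w_max_ie : nw);
          }
        } else {
          // interneuron spike: symmetric STDP with every partner
          for (int j = 0; j < N; ++j) {
            if (j == i) continue;
            As_post[j] = rest_post +
              (As_post[j] - rest_post) * std::exp(-(t - ts_post[j]) / sy_tau_post);
            ts_post[j] = t;
            As_pre[j] = rest_pre +
              (As_pre[j] - rest_pre) * std::exp(-(t - ts_pre[j]) / sy_tau_pre);
            ts_pre[j] = t;
            double nw = Wl(i, j) + As_post[j];
            Wl(i, j) = nw < 0 ? 0 : (nw > w_max_ie ? w_max_ie : nw);
            double bnd = (j < n_exc) ? w_max_ei : w_max_ie;
            nw = Wl(j, i) + As_pre[j];
            Wl(j, i) = nw < 0 ? 0 : (nw > bnd ? bnd : nw);
          }
        }
        // symmetric own-trace increments (any spike, either endpoint role)
        As_pre[i] = rest_pre +
          (As_pre[i] - rest_pre) * std::exp(-(t - ts_pre[i]) / sy_tau_pre)
          + sy_dA_pre;
        ts_pre[i] = t;
        As_post[i] = rest_post +
          (As_post[i] - rest_post) * std::exp(-(t - ts_post[i]) / sy_tau_post)
          + sy_dA_post;
        ts_post[i] = t;
      }

      // motor-cortex neuron
      if (t - last_mc <= refractory_ms) {
        v_mc = 0.0;
      } else if (v_mc >= v_thresh) {
        v_mc = 0.0; last_mc = t;
        if (record_raster && (int)ras_n.size() < raster_max) {
          ras_n.push_back(N); ras_t.push_back(t);
        }
        if (in_resp) {
          ++mc_count;
          if (ISNA(first_lat)) first_lat = t_rel - trig_on;
        }
        if (plastic_da) { // MC as postsynaptic: eligibility picks up pre traces
          Am_post = Am_post * std::exp(-(t - tm_post) / da_tau_post)
            + da_dA_post;
          tm_post = t;
          for (int j = 0; j < n_exc; ++j) {
            Am_pre[j] *= std::exp(-(t - tm_pre[j]) / da_tau_pre);
            c[j] = c[j] * std::exp(-(t - tm_pre[j]) / tau_c) + Am_pre[j];
            tm_pre[j] = t;
          }
        }
      }

      // continuous dopamine dynamics: d, s and weight integration
      if (plastic_da) {
        d *= dec_d;
        for (int j = 0; j < n_exc; ++j) {
          double cj = c[j] * std::exp(-(t - tm_pre[j]) / tau_c);
          double cd = cj * d;
          s[j] = cd + (s[j] - cd) * dec_s;
          if (s[j] != 0.0) {
            double nw = w_mc[j] + dt * s[j];
            w_mc[j] = nw < 0 ? 0 : (nw > w_mc_max ? w_mc_max : nw);
          }
        }
      }
    }

    // decision at response-window close
    bool pressed = mc_count >= mc_threshold;
    bool is_target = trial_label[tr] > decision_x;
    out_pressed[tr] = pressed;
    out_correct[tr] = pressed == is_target;
    out_reward[tr] = pressed ? (is_target ? 1 : -1) : 0;
    out_mc[tr] = mc_count;
    out_lat[tr] = first_lat;
    if (plastic_da)
      pending_reward = pressed ? (is_target ? reward_magnitude
                                            : -reward_magnitude) : 0.0;

    if (snapshot_every > 0 && (tr + 1) % snapshot_every == 0 &&
        snap_i < n_snap) {
      for (int j = 0; j < n_exc; ++j) mc_snap(snap_i, j) = w_mc[j];
      double s00 = 0, s11 = 0, sx = 0, sei = 0, sie = 0;
      int c00 = 0, c11 = 0, cx = 0, cei = 0, cie = 0;
      for (int i = 0; i < N; ++i) for (int j = 0; j < N; ++j) {
        if (i == j) continue;
        if (i < n_exc && j < n_exc) {
          if (group[i] == 0 && group[j] == 0) { s00 += Wl(i, j); ++c00; }
          else if (group[i] == 1 && group[j] == 1) { s11 += Wl(i, j); ++c11; }
          else { sx += Wl(i, j); ++cx; }
        } else if (i < n_exc) { sei += Wl(i, j); ++cei; }
        else { sie += Wl(i, j); ++cie; }
      }
      ee_snap(snap_i, 0) = c00 ? s00 / c00 : 0;
      ee_snap(snap_i, 1) = c11 ? s11 / c11 : 0;
      ee_snap(snap_i, 2) = cx ? sx / cx : 0;
      ee_snap(snap_i, 3) = cei ? sei / cei : 0;
      ee_snap(snap_i, 4) = cie ? sie / cie : 0;
      snap_trial[snap_i] = tr + 1;
      ++snap_i;
    }
    if ((tr & 15) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["pressed"] = out_pressed, _["correct"] = out_correct,
    _["reward_sign"] = out_reward, _["mc_spikes"] = out_mc,
    _["latency"] = out_lat,
    _["win_counts"] = win_counts,
    _["w_gnw"] = Wl, _["w_mc"] = NumericVector(w_mc.begin(), w_mc.end()),
    _["mc_snapshots"] = mc_snap, _["ee_snapshots"] = ee_snap,
    _["snap_trial"] = snap_trial,
    _["raster_neuron"] = IntegerVector(ras_n.begin(), ras_n.end()),
    _["raster_t"] = NumericVector(ras_t.begin(), ras_t.end()),
    _["diag"] = diag);
}
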