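// Clock-driven core of the balanced-network simulator.
//
// Integration is exact for the linear (V, g_e, g_i) subsystem: over one step
// of length dt the membrane relaxes towards V_inf while each synaptic trace
// decays exponentially, and the cross terms are propagated with the closed
// form of the driven first-order ODE.  Threshold crossings are detected after
// the update; emitted spikes are delivered to postsynaptic traces at the end
// of the step, so transmission takes effect one step (dt) later.
//
// STDP bookkeeping uses lazily-decayed eligibility traces, which is exactly
// equivalent to all-to-all pair summation with exponential kernels.  Pair
// ordering within one step follows the rule that t_post - t_pre = 0 belongs
// to the depression branch: postsynaptic trace increments are applied before
// depression-on-pre, presynaptic increments after potentiation-on-post.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct StdpRule {
  bool on = false;
  double a_plus = 0.0;    // effective amplitude (already scaled for additive)
  double a_minus = 0.0;
  double tau_plus = 20.0; // ms
  double tau_minus = 20.0;
  double w_max = 1.0;
  int mode = 0;           // 0 additive, 1 partly multiplicative, 2 fully
  double amp_plus(double w) const {
    if (mode == 2) return a_plus * (1.0 - w / w_max);
    return a_plus;
  }
  double amp_minus(double w) const {
    if (mode >= 1) return a_minus * (w / w_max);
    return a_minus;
  }
};

// lazily decayed trace array
struct TraceArr {
  std::vector<double> val;
  std::vector<int64_t> step;
  double decay_per_step = 1.0;
  void init(int n, double tau_ms, double dt) {
    val.assign(n, 0.0);
    step.assign(n, 0);
    decay_per_step = std::exp(-dt / tau_ms);
  }
  inline double get(int i, int64_t now) {
    int64_t lag = now - step[i];
    if (lag > 0) {
      val[i] *= std::pow(decay_per_step, (double)lag);
      step[i] = now;
    }
    return val[i];
  }
  inline void bump(int i, int64_t now) {
    get(i, now);
    val[i] += 1.0;
  }
};

inline double list_num(const List& l, const char* k, double def) {
  if (!l.containsElementNamed(k)) return def;
  return as<double>(l[k]);
}
inline int list_int(const List& l, const char* k, int def) {
  if (!l.containsElementNamed(k)) return def;
  return as<int>(l[k]);
}
inline bool list_bool(const List& l, const char* k, bool def) {
  if (!l.containsElementNamed(k)) return def;
  return as<bool>(l[k]);
}
inline std::string list_str(const List& l, const char* k, std::string def) {
  if (!l.containsElementNamed(k)) return def;
  return as<std::string>(l[k]);
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(int n_e, int n_i,
                  IntegerVector edge_pre, IntegerVector edge_post,
                  NumericVector edge_w,
                  List neuron, List synapse, List drive,
                  List plasticity, List stimulus,
                  NumericVector init_V, NumericVector init_ge,
                  NumericVector init_gi, IntegerVector init_refr,
                  double t0, double duration, double dt,
                  List record) {
  const int n = n_e + n_i;
  const R_xlen_t m = edge_pre.size();
  if (edge_post.size() != m || edge_w.size() != m)
    stop("edge arrays must have equal length");
  if (init_V.size() != n) stop("init_V has wrong length");

  // ---- parameters -------------------------------------------------------
  const double tau_m = list_num(neuron, "tau_m", 20.0);
  const double E_L = list_num(neuron, "E_L", -60.0);
  const double V_thres = list_num(neuron, "V_thres", -50.0);
  const double V_reset = list_num(neuron, "V_reset", -60.0);
  const double tau_ref = list_num(neuron, "tau_ref", 2.0);

  const double tau_e = list_num(synapse, "tau_e", 5.0);
  const double tau_i = list_num(synapse, "tau_i", 10.0);
  const double c_e = list_num(synapse, "c_e_norm", 1.0);
  const double c_i_mag = std::fabs(list_num(synapse, "c_i_norm", -9.0));
  const double w_e_max = list_num(synapse, "w_e_max", 20.0);
  const double w_i_max = list_num(synapse, "w_i_max", 5.0);

  const std::string drive_mode = list_str(drive, "mode", "constant");
  const double depol = list_num(drive, "depolarization", 11.0);
  const double ext_rate = list_num(drive, "rate", 2200.0); // Hz per neuron
  const double ext_w = list_num(drive, "weight", 1.0);

  // propagator coefficients
  const double Em = std::exp(-dt / tau_m);
  const double Ee = std::exp(-dt / tau_e);
  const double Ei = std::exp(-dt / tau_i);
  const double fe = c_e * (tau_e / (tau_e - tau_m)) * (Ee - Em);
  const double fi = c_i_mag * (tau_i / (tau_i - tau_m)) * (Ei - Em);
  const double v_inf = (drive_mode == "constant") ? E_L + depol : E_L;
  const int refr_steps = (int)std::ceil(tau_ref / dt - 1e-9);

  // ---- plasticity config ------------------------------------------------
  StdpRule ee, ie;
  std::string homeo = "none";
  double norm_interval = 100.0, norm_target = 1.0;
  double gamma = 1e-6, nu0 = 0.0, scale_interval = 50.0, rate_window = 100000.0;
  if (plasticity.size() > 0 && list_bool(plasticity, "enabled", false)) {
    if (plasticity.containsElementNamed("ee")) {
      List p = plasticity["ee"];
      ee.on = list_bool(p, "on", false);
      ee.a_plus = list_num(p, "a_plus_eff", 0.02);
      ee.a_minus = list_num(p, "a_minus_eff", 0.021);
      ee.tau_plus = list_num(p, "tau_plus", 20.0);
      ee.tau_minus = list_num(p, "tau_minus", 20.0);
      ee.w_max = w_e_max;
      ee.mode = list_int(p, "mode", 0);
    }
    if (plasticity.containsElementNamed("ie")) {
      List p = plasticity["ie"];
      ie.on = list_bool(p, "on", false);
      ie.a_plus = list_num(p, "a_plus_eff", 0.02);
      ie.a_minus = list_num(p, "a_minus_eff", 0.005);
      ie.tau_plus = list_num(p, "tau_plus", 20.0);
      ie.tau_minus = list_num(p, "tau_minus", 20.0);
      ie.w_max = w_i_max;
      ie.mode = 0;
    }
    homeo = list_str(plasticity, "homeostasis", "none");
    norm_interval = list_num(plasticity, "norm_interval", 100.0);
    norm_target = list_num(plasticity, "norm_target", 1.0);
    gamma = list_num(plasticity, "gamma", 1e-6);
    nu0 = list_num(plasticity, "nu_0", 0.0);
    scale_interval = list_num(plasticity, "scale_interval", 50.0);
    rate_window = list_num(plasticity, "rate_window", 100.0) * 1000.0; // s -> ms
  }
  const bool any_stdp = ee.on || ie.on;
  const bool do_norm = homeo == "normalization";
  const bool do_scale = homeo == "scaling";

  // ---- stimulus ---------------------------------------------------------
  std::vector<int> stim_ids;
  double stim_onset = -1.0, stim_pulse = 0.5, stim_gap = 2.0, stim_amp = 1000.0;
  int stim_npulse = 0;
  if (stimulus.size() > 0 && stimulus.containsElementNamed("target_ids")) {
    IntegerVector ids = stimulus["target_ids"];
    stim_ids.assign(ids.begin(), ids.end());
    stim_onset = list_num(stimulus, "onset", 0.0);
    stim_pulse = list_num(stimulus, "pulse_duration", 0.5);
    stim_gap = list_num(stimulus, "inter_pulse_gap", 2.0);
    stim_amp = list_num(stimulus, "amplitude", 1000.0);
    stim_npulse = list_int(stimulus, "n_pulses", 2);
  }

  // ---- recording --------------------------------------------------------
  const double record_from = list_num(record, "record_from", 0.0); // absolute ms
  const double snapshot_interval = list_num(record, "snapshot_interval", 0.0);
  const double summary_interval = list_num(record, "summary_interval", 0.0);
  const double rate_ceiling = list_num(record, "rate_ceiling", 0.0); // Hz, 0 = off
  IntegerVector mon_ids0;
  if (record.containsElementNamed("monitor_ids"))
    mon_ids0 = as<IntegerVector>(record["monitor_ids"]);
  const std::vector<int> mon_ids(mon_ids0.begin(), mon_ids0.end());

  // ---- connectivity: CSR by presynaptic cell ---------------------------
  std::vector<double> w(edge_w.begin(), edge_w.end());
  std::vector<int> out_ptr(n + 1, 0), out_tgt(m), out_eid(m);
  {
    std::vector<int> cnt(n, 0);
    for (R_xlen_t e = 0; e < m; ++e) cnt[edge_pre[e]]++;
    for (int i = 0; i < n; ++i) out_ptr[i + 1] = out_ptr[i] + cnt[i];
    std::vector<int> pos(out_ptr.begin(), out_ptr.end() - 1);
    for (R_xlen_t e = 0; e < m; ++e) {
      int j = edge_pre[e];
      out_tgt[pos[j]] = edge_post[e];
      out_eid[pos[j]] = (int)e;
      pos[j]++;
    }
  }
  // incoming E-E and I-E lists per excitatory cell (for on-post STDP and
  // homeostasis)
  std::vector<int> in_ee_ptr(n_e + 1, 0), in_ee_src, in_ee_eid;
  std::vector<int> in_ie_ptr(n_e + 1, 0), in_ie_src, in_ie_eid;
  {
    std::vector<int> cee(n_e, 0), cie(n_e, 0);
    for (R_xlen_t e = 0; e < m; ++e) {
      int pst = edge_post[e];
      if (pst < n_e) {
        if (edge_pre[e] < n_e) cee[pst]++; else cie[pst]++;
      }
    }
    for (int i = 0; i < n_e; ++i) {
      in_ee_ptr[i + 1] = in_ee_ptr[i] + cee[i];
      in_ie_ptr[i + 1] = in_ie_ptr[i] + cie[i];
    }
    in_ee_src.resize(in_ee_ptr[n_e]); in_ee_eid.resize(in_ee_ptr[n_e]);
    in_ie_src.resize(in_ie_ptr[n_e]); in_ie_eid.resize(in_ie_ptr[n_e]);
    std::vector<int> pee(in_ee_ptr.begin(), in_ee_ptr.end() - 1);
    std::vector<int> pie(in_ie_ptr.begin(), in_ie_ptr.end() - 1);
    for (R_xlen_t e = 0; e < m; ++e) {
      int pst = edge_post[e];
      if (pst >= n_e) continue;
      if (edge_pre[e] < n_e) {
        in_ee_src[pee[pst]] = edge_pre[e]; in_ee_eid[pee[pst]] = (int)e; pee[pst]++;
      } else {
        in_ie_src[pie[pst]] = edge_pre[e]; in_ie_eid[pie[pst]] = (int)e; pie[pst]++;
      }
    }
  }
  // E-E edge ids (snapshot / summary bookkeeping)
  std::vector<int> ee_eid, ie_eid;
  for (R_xlen_t e = 0; e < m; ++e) {
    if (edge_post[e] < n_e) {
      if (edge_pre[e] < n_e) ee_eid.push_back((int)e);
      else ie_eid.push_back((int)e);
    }
  }

  // ---- state ------------------------------------------------------------
  std::vector<double> V(init_V.begin(), init_V.end());
  std::vector<double> g_e(n, 0.0), g_i(n, 0.0);
  if (init_ge.size() == n) std::copy(init_ge.begin(), init_ge.end(), g_e.begin());
  if (init_gi.size() == n) std::copy(init_gi.begin(), init_gi.end(), g_i.begin());
  std::vector<int> refr(n, 0);
  if (init_refr.size() == n) std::copy(init_refr.begin(), init_refr.end(), refr.begin());

  TraceArr x_pre_ee, x_post_ee, x_pre_ie, x_post_ie;
  if (ee.on) { x_pre_ee.init(n_e, ee.tau_plus, dt); x_post_ee.init(n_e, ee.tau_minus, dt); }
  if (ie.on) { x_pre_ie.init(n_i, ie.tau_plus, dt); x_post_ie.init(n_e, ie.tau_minus, dt); }

  // sliding-window spike counts for synaptic scaling
  int n_bins = 0, cur_bin = 0;
  std::vector<uint16_t> rate_bins; // n_e x n_bins circular
  std::vector<int> rate_tot;       // current window totals
  if (do_scale) {
    n_bins = std::max(1, (int)std::round(rate_window / scale_interval));
    rate_bins.assign((size_t)n_e * n_bins, 0);
    rate_tot.assign(n_e, 0);
  }

  const int64_t n_steps = (int64_t)std::llround(duration / dt);
  const int64_t norm_every = do_norm ? std::max((int64_t)1, (int64_t)std::llround(norm_interval / dt)) : 0;
  const int64_t scale_every = do_scale ? std::max((int64_t)1, (int64_t)std::llround(scale_interval / dt)) : 0;
  const int64_t snap_every = snapshot_interval > 0 ? std::max((int64_t)1, (int64_t)std::llround(snapshot_interval / dt)) : 0;
  const int64_t summ_every = summary_interval > 0 ? std::max((int64_t)1, (int64_t)std::llround(summary_interval / dt)) : 0;

  std::vector<double> spk_t;
  std::vector<int> spk_id;
  std::vector<int64_t> spike_count(n, 0);
  std::vector<int> step_spikes;
  step_spikes.reserve(256);

  List snapshots;
  std::vector<double> snap_times;
  std::vector<double> summary_rows; // t, mean_ee, var_ee, mean_ie, var_ie, re, ri
  int64_t last_sum_spk_e = 0, last_sum_spk_i = 0;

  NumericMatrix mon_V(mon_ids.empty() ? 0 : (int)(n_steps + 1), (int)mon_ids.size());
  if (!mon_ids.empty())
    for (size_t k = 0; k < mon_ids.size(); ++k) mon_V(0, (int)k) = V[mon_ids[k]];

  // divergence guard bookkeeping: excitatory spikes per second
  std::vector<double> sec_rates;
  int64_t sec_spk = 0;
  const int64_t steps_per_sec = (int64_t)std::llround(1000.0 / dt);
  bool aborted = false;

  auto class_summary = [&](const std::vector<int>& ids, double& mean, double& var) {
    if (ids.empty()) { mean = NA_REAL; var = NA_REAL; return; }
    double s = 0, s2 = 0;
    for (int e : ids) { s += w[e]; s2 += w[e] * w[e]; }
    double mu = s / ids.size();
    mean = mu;
    var = s2 / ids.size() - mu * mu;
  };

  RNGScope rng;

  // ---- main loop --------------------------------------------------------
  for (int64_t k = 0; k < n_steps && !aborted; ++k) {
    const double t_spk = t0 + (k + 1) * dt; // time assigned to this step's spikes
    step_spikes.clear();

    // membrane + trace propagation (uses traces at step start)
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) {
        refr[i]--;
        V[i] = V_reset;
      } else {
        V[i] = v_inf + (V[i] - v_inf) * Em + fe * g_e[i] - fi * g_i[i];
      }
      g_e[i] *= Ee;
      g_i[i] *= Ei;
    }

    // stimulation pulses: extra constant current for targeted cells
    if (stim_npulse > 0) {
      const double tr = t0 + (k + 0.5) * dt - stim_onset; // step midpoint
      if (tr >= 0 && tr < stim_npulse * (stim_pulse + stim_gap)) {
        const double period = stim_pulse + stim_gap;
        double ph = tr - std::floor(tr / period) * period;
        if (ph < stim_pulse) {
          const double add = stim_amp * (1.0 - Em);
          for (int i : stim_ids) if (refr[i] == 0) V[i] += add;
        }
      }
    }

    // threshold crossing
    for (int i = 0; i < n; ++i) {
      if (refr[i] == 0 && V[i] >= V_thres) {
        V[i] = V_reset;
        refr[i] = refr_steps;
        step_spikes.push_back(i);
        spike_count[i]++;
        if (t_spk >= record_from) { spk_t.push_back(t_spk); spk_id.push_back(i); }
        if (i < n_e) sec_spk++;
        if (do_scale && i < n_e) {
          rate_bins[(size_t)i * n_bins + cur_bin]++;
          rate_tot[i]++;
        }
      }
    }

    if (!std::isfinite(V[0]))
      stop("non-finite membrane potential encountered at t = %f ms", t_spk);

    // plasticity: post-trace bump -> depression-on-pre -> potentiation-on-post
    // -> pre-trace bump  (so that dt = 0 pairs take the depression branch)
    if (any_stdp && !step_spikes.empty()) {
      for (int i : step_spikes) {
        if (i < n_e) {
          if (ee.on) x_post_ee.bump(i, k);
          if (ie.on) x_post_ie.bump(i, k);
        }
      }
      for (int j : step_spikes) { // presynaptic role: depression
        const bool is_e = j < n_e;
        if ((is_e && ee.on) || (!is_e && ie.on)) {
          const StdpRule& r = is_e ? ee : ie;
          TraceArr& xp = is_e ? x_post_ee : x_post_ie;
          for (int q = out_ptr[j]; q < out_ptr[j + 1]; ++q) {
            int tgt = out_tgt[q];
            if (tgt >= n_e) continue; // only *-E connections are plastic
            int e = out_eid[q];
            double nw = w[e] - r.amp_minus(w[e]) * xp.get(tgt, k);
            w[e] = nw < 0.0 ? 0.0 : nw;
          }
        }
      }
      for (int i : step_spikes) { // postsynaptic role: potentiation
        if (i >= n_e) continue;
        if (ee.on) {
          for (int q = in_ee_ptr[i]; q < in_ee_ptr[i + 1]; ++q) {
            int e = in_ee_eid[q];
            double nw = w[e] + ee.amp_plus(w[e]) * x_pre_ee.get(in_ee_src[q], k);
            w[e] = nw > w_e_max ? w_e_max : nw;
          }
        }
        if (ie.on) {
          for (int q = in_ie_ptr[i]; q < in_ie_ptr[i + 1]; ++q) {
            int e = in_ie_eid[q];
            double nw = w[e] + ie.amp_plus(w[e]) * x_pre_ie.get(in_ie_src[q] - n_e, k);
            w[e] = nw > w_i_max ? w_i_max : nw;
          }
        }
      }
      for (int j : step_spikes) {
        if (j < n_e) { if (ee.on) x_pre_ee.bump(j, k); }
        else if (ie.on) x_pre_ie.bump(j - n_e, k);
      }
    }

    // spike delivery (takes effect from the next step on)
    for (int j : step_spikes) {
      const bool is_e = j < n_e;
      for (int q = out_ptr[j]; q < out_ptr[j + 1]; ++q) {
        if (is_e) g_e[out_tgt[q]] += w[out_eid[q]];
        else g_i[out_tgt[q]] += w[out_eid[q]];
      }
    }

    // external Poisson drive (superposed train split over the population)
    if (drive_mode == "poisson" && ext_rate > 0) {
      double lam = (double)n * ext_rate * dt / 1000.0;
      int K = (int)R::rpois(lam);
      for (int q = 0; q < K; ++q) {
        int i = (int)(unif_rand() * n);
        if (i >= n) i = n - 1;
        g_e[i] += ext_w;
      }
    }

    // homeostasis
    if (do_norm && (k + 1) % norm_every == 0) {
      for (int i = 0; i < n_e; ++i) {
        int a = in_ee_ptr[i], b = in_ee_ptr[i + 1];
        if (b == a) continue;
        double s = 0;
        for (int q = a; q < b; ++q) s += w[in_ee_eid[q]];
        if (s <= 0) continue; // degenerate all-zero vector: left untouched
        double f = (b - a) * norm_target / s;
        for (int q = a; q < b; ++q) {
          double nw = w[in_ee_eid[q]] * f;
          w[in_ee_eid[q]] = nw > w_e_max ? w_e_max : nw;
        }
      }
    }
    if (do_scale && (k + 1) % scale_every == 0) {
      double win_s = std::min((double)(k + 1) * dt, rate_window) / 1000.0;
      double dt_s = scale_interval / 1000.0;
      for (int i = 0; i < n_e; ++i) {
        double nu = rate_tot[i] / win_s;
        if (nu == nu0) continue;
        double fac = gamma * (nu - nu0) * dt_s;
        for (int q = in_ee_ptr[i]; q < in_ee_ptr[i + 1]; ++q) {
          int e = in_ee_eid[q];
          double nw = w[e] - fac * w[e] * w[e];
          w[e] = nw < 0 ? 0 : (nw > w_e_max ? w_e_max : nw);
        }
      }
      cur_bin = (cur_bin + 1) % n_bins;
      for (int i = 0; i < n_e; ++i) {
        rate_tot[i] -= rate_bins[(size_t)i * n_bins + cur_bin];
        rate_bins[(size_t)i * n_bins + cur_bin] = 0;
      }
    }

    // recording
    if (!mon_ids.empty())
      for (size_t q = 0; q < mon_ids.size(); ++q) mon_V((int)(k + 1), (int)q) = V[mon_ids[q]];
    if (snap_every > 0 && (k + 1) % snap_every == 0) {
      NumericVector sn(ee_eid.size());
      for (size_t q = 0; q < ee_eid.size(); ++q) sn[q] = w[ee_eid[q]];
      snapshots.push_back(sn);
      snap_times.push_back(t0 + (k + 1) * dt);
    }
    if (summ_every > 0 && (k + 1) % summ_every == 0) {
      double me, ve, mi, vi;
      class_summary(ee_eid, me, ve);
      class_summary(ie_eid, mi, vi);
      int64_t tot_e = 0, tot_i = 0;
      for (int i = 0; i < n_e; ++i) tot_e += spike_count[i];
      for (int i = n_e; i < n; ++i) tot_i += spike_count[i];
      double dt_s = summ_every * dt / 1000.0;
      double re = n_e > 0 ? (tot_e - last_sum_spk_e) / dt_s / n_e : NA_REAL;
      double ri = n_i > 0 ? (tot_i - last_sum_spk_i) / dt_s / n_i : NA_REAL;
      last_sum_spk_e = tot_e; last_sum_spk_i = tot_i;
      double row[7] = {t0 + (k + 1) * dt, me, ve, mi, vi, re, ri};
      summary_rows.insert(summary_rows.end(), row, row + 7);
    }
    if (rate_ceiling > 0 && (k + 1) % steps_per_sec == 0) {
      sec_rates.push_back(n_e > 0 ? (double)sec_spk / n_e : 0.0);
      sec_spk = 0;
      if (sec_rates.size() >= 10) {
        double s = 0;
        for (size_t q = sec_rates.size() - 10; q < sec_rates.size(); ++q) s += sec_rates[q];
        if (s / 10.0 > rate_ceiling) aborted = true;
      }
    }
  }

  // flush final trace decay so returned weights correspond to end time
  NumericVector w_out(w.begin(), w.end());
  NumericVector V_out(V.begin(), V.end());
  NumericVector ge_out(g_e.begin(), g_e.end());
  NumericVector gi_out(g_i.begin(), g_i.end());
  IntegerVector refr_out(refr.begin(), refr.end());
  IntegerVector cnt_out(n);
  for (int i = 0; i < n; ++i) cnt_out[i] = (int)spike_count[i];

  NumericMatrix summary((int)(summary_rows.size() / 7), 7);
  for (int r = 0; r < summary.nrow(); ++r)
    for (int c = 0; c < 7; ++c) summary(r, c) = summary_rows[(size_t)r * 7 + c];

  return List::create(
      _["spike_time"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["spike_count"] = cnt_out,
      _["weights"] = w_out,
      _["V"] = V_out, _["g_e"] = ge_out, _["g_i"] = gi_out,
      _["refractory"] = refr_out,
      _["t_end"] = t0 + n_steps * dt,
      _["monitor_V"] = mon_V,
      _["snapshots"] = snapshots,
      _["snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end()),
      _["summary"] = summary,
      _["aborted"] = aborted);
}

// Distance-dependent edge sampling on the unit torus.  Every ordered pair is
// tested with one uniform draw; the Gaussian profile of the *presynaptic*
// cell's class sets the acceptance probability.
// [[Rcpp::export]]
List cpp_torus_edges(NumericVector u, NumericVector v, int n_e,
                     double eps_e, double sig_e, double eps_i, double sig_i) {
  const int n = u.size();
  std::vector<int> pre, post;
  pre.reserve(n * 8); post.reserve(n * 8);
  RNGScope rng;
  for (int a = 0; a < n; ++a) {
    const bool is_e = a < n_e;
    const double eps = is_e ? eps_e : eps_i;
    const double inv2s2 = 1.0 / (2.0 * (is_e ? sig_e * sig_e : sig_i * sig_i));
    if (eps <= 0) continue;
    const double ua = u[a], va = v[a];
    for (int b = 0; b < n; ++b) {
      if (b == a) continue;
      double r = unif_rand();
      if (r >= eps) continue; // p <= eps always
      double dx = std::fabs(ua - u[b]); if (dx > 0.5) dx = 1.0 - dx;
      double dy = std::fabs(va - v[b]); if (dy > 0.5) dy = 1.0 - dy;
      double p = eps * std::exp(-(dx * dx + dy * dy) * inv2s2);
      if (r < p) { pre.push_back(a); post.push_back(b); }
    }
  }
  return List::create(_["pre"] = IntegerVector(pre.begin(), pre.end()),
                      _["post"] = IntegerVector(post.begin(), post.end()));
}
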