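// Reduced models used for the mean-field validation experiments:
//  * a two-cell inhibitory pair with a plastic delta synapse (stationary
//    weight of inhibitory STDP),
//  * a two-cell excitatory pair with a frozen delta synapse (average STDP
//    drift as a function of the weight),
//  * a fan-in competition setup (many Poisson inputs onto one LIF cell with
//    STDP and weight normalization).
// All use nearest-neighbour spike pairing where the derivations do, and the
// same one-step (dt) transmission delay convention as the network engine.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Two integrate-and-fire cells (no leak: linear rise under small Poisson
// kicks), connected pre -> post by an inhibitory delta synapse under
// additive Hebbian inhibitory STDP with nearest-neighbour pairing.
// Rates are controlled through the kick rate: R = nu * (V_thres-V_rest)/kick.
// [[Rcpp::export]]
List cpp_two_neuron_inhibitory(double nu0, double nu_pre, double duration_s,
                               double dt, double kick, double w_init,
                               double w_cap, double a_plus, double a_minus,
                               double tau, double delta_v,
                               double record_every_s, double tail_frac) {
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt);
  const double lam_post = nu0 * delta_v / kick * dt / 1000.0;
  const double lam_pre = nu_pre * delta_v / kick * dt / 1000.0;
  double v_post = 0.0, v_pre = 0.0; // measured above V_rest
  double w = w_init;
  long last_post = -1000000000L, last_pre = -1000000000L;
  const long rec_every = record_every_s > 0
      ? (long)std::llround(record_every_s * 1000.0 / dt) : 0;
  std::vector<double> traj_t, traj_w;
  double tail_sum = 0.0;
  long tail_n = 0;
  const long tail_from = (long)((1.0 - tail_frac) * n_steps);
  long n_post_spk = 0;
  RNGScope rng;
  for (long k = 0; k < n_steps; ++k) {
    v_pre += kick * R::rpois(lam_pre);
    v_post += kick * R::rpois(lam_post);
    if (v_pre >= delta_v) {
      v_pre = 0.0;
      v_post -= w; // inhibitory delta PSP (no lower bound: pure delay model)
      if (last_post > -1000000000L) {
        w -= a_minus * std::exp(-(k - last_post) * dt / tau);
        if (w < 0) w = 0;
      }
      last_pre = k;
    }
    if (v_post >= delta_v) {
      v_post = 0.0;
      if (last_pre > -1000000000L && k > last_pre) {
        w += a_plus * std::exp(-(k - last_pre) * dt / tau);
        if (w > w_cap) w = w_cap;
      }
      last_post = k;
      n_post_spk++;
    }
    if (rec_every > 0 && (k + 1) % rec_every == 0) {
      traj_t.push_back((k + 1) * dt / 1000.0);
      traj_w.push_back(w);
    }
    if (k >= tail_from) { tail_sum += w; tail_n++; }
  }
  return List::create(_["w_final"] = w,
                      _["w_stationary"] = tail_n ? tail_sum / tail_n : w,
                      _["post_rate"] = n_post_spk / duration_s,
                      _["t"] = NumericVector(traj_t.begin(), traj_t.end()),
                      _["w"] = NumericVector(traj_w.begin(), traj_w.end()));
}

// Two LIF cells A (pre) and B (post) driven by independent Poisson delta
// input (n_inputs synapses at in_rate Hz, in_w mV each), connected A -> B by
// a frozen delta synapse of strength w.  STDP updates (nearest-neighbour)
// are accumulated but never applied.  Returns the accumulated update, spike
// counts, and a subthreshold membrane-potential histogram for B.
// [[Rcpp::export]]
List cpp_two_neuron_excitatory(double w, double duration_s, double dt,
                               double n_inputs, double in_rate, double in_w,
                               double tau_m, double E_L, double V_thres,
                               double V_reset, double tau_ref,
                               double a_plus, double a_minus, double tau_stdp,
                               double hist_lo, double hist_hi, int hist_bins) {
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt);
  const double lam = n_inputs * in_rate * dt / 1000.0; // kicks per step
  const double Em = std::exp(-dt / tau_m);
  const int refr_steps = (int)std::ceil(tau_ref / dt - 1e-9);
  double vA = E_L, vB = E_L;
  int refA = 0, refB = 0;
  bool pendingB = false; // synaptic kick from A arriving next step
  long lastA = -1000000000L, lastB = -1000000000L;
  double dw = 0.0;
  long nA = 0, nB = 0;
  double isi_sum = 0.0, isi_sum2 = 0.0;
  long n_isi = 0, prevB = -1;
  long n_trig = 0;
  double dw_trig = 0.0, last_dep_A = 0.0, dw_trig_dep = 0.0;
  std::vector<double> hist(hist_bins, 0.0);
  const double hist_w = (hist_hi - hist_lo) / hist_bins;
  RNGScope rng;
  for (long k = 0; k < n_steps; ++k) {
    // A ------------------------------------------------------------------
    if (refA > 0) { refA--; vA = V_reset; }
    else {
      vA = E_L + (vA - E_L) * Em + in_w * R::rpois(lam);
    }
    bool spkA = false;
    if (refA == 0 && vA >= V_thres) {
      vA = V_reset; refA = refr_steps; spkA = true; nA++;
    }
    // B ------------------------------------------------------------------
    if (refB > 0) { refB--; vB = V_reset; }
    else {
      vB = E_L + (vB - E_L) * Em + in_w * R::rpois(lam);
      if (pendingB) vB += w;
    }
    pendingB = false;
    if (refB == 0 && vB >= V_thres) {
      vB = V_reset; refB = refr_steps; nB++;
      if (lastA > -1000000000L && k > lastA) {
        dw += a_plus * std::exp(-(k - lastA) * dt / tau_stdp);
        if (k - lastA == 1) { // immediate trigger by the synaptic kick
          n_trig++;
          dw_trig += a_plus * std::exp(-dt / tau_stdp);
          dw_trig_dep += last_dep_A;
        }
      }
      if (prevB >= 0) {
        double isi = (k - prevB) * dt; // ms
        isi_sum += isi; isi_sum2 += isi * isi; n_isi++;
      }
      prevB = k;
      lastB = k;
    } else if (refB == 0) {
      int b = (int)((vB - hist_lo) / hist_w);
      if (b >= 0 && b < hist_bins) hist[b] += 1.0;
    }
    if (spkA) {
      pendingB = true;
      last_dep_A = 0.0;
      if (lastB > -1000000000L) {
        last_dep_A = -a_minus * std::exp(-(k - lastB) * dt / tau_stdp);
        dw += last_dep_A;
      }
      lastA = k;
    }
  }
  double isi_mean = n_isi ? isi_sum / n_isi : NA_REAL;
  double isi_var = n_isi > 1 ? isi_sum2 / n_isi - isi_mean * isi_mean
                             : NA_REAL;
  return List::create(_["dw_total"] = dw, _["n_pre"] = (double)nA,
                      _["n_post"] = (double)nB,
                      _["rate_pre"] = nA / duration_s,
                      _["rate_post"] = nB / duration_s,
                      _["isi_mean"] = isi_mean, _["isi_var"] = isi_var,
                      _["n_trigger"] = (double)n_trig, _["dw_trigger"] = dw_trig,
                      _["dw_trigger_dep"] = dw_trig_dep,
                      _["hist"] = NumericVector(hist.begin(), hist.end()));
}

// n_syn Poisson inputs with individual rates converging onto one LIF cell
// through current-based exponential synapses; all-to-all additive STDP with
// postsynaptic weight normalization at a fixed cadence.
// [[Rcpp::export]]
List cpp_fan_in(NumericVector rates, double duration_s, double dt,
                double drive, double tau_m, double E_L, double V_thres,
                double V_reset, double tau_ref, double tau_e, double c_e,
                double a_plus, double a_minus, double tau_plus,
                double tau_minus, double w_max, double w_init,
                double norm_interval, double norm_target,
                double record_every_s) {
  const int ns = rates.size();
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt);
  const double Em = std::exp(-dt / tau_m);
  const double Ee = std::exp(-dt / tau_e);
  const double fe = c_e * (tau_e / (tau_e - tau_m)) * (Ee - Em);
  const int refr_steps = (int)std::ceil(tau_ref / dt - 1e-9);
  const double v_inf = E_L + drive;
  const double dec_plus = std::exp(-dt / tau_plus);
  const double dec_minus = std::exp(-dt / tau_minus);

  std::vector<double> cum(ns);
  double tot = 0;
  for (int i = 0; i < ns; ++i) { tot += rates[i]; cum[i] = tot; }
  const double lam = tot * dt / 1000.0;

  std::vector<double> w(ns, w_init), x_pre(ns, 0.0);
  std::vector<long> x_step(ns, 0);
  double x_post = 0.0;
  long x_post_step = 0;
  double V = E_L, g = 0.0;
  int refr = 0;
  long n_spk = 0;
  const long norm_every = (long)std::llround(norm_interval / dt);
  const long rec_every = record_every_s > 0
      ? (long)std::llround(record_every_s * 1000.0 / dt) : 0;
  std::vector<double> traj; // rows: t, w[0..ns-1]
  std::vector<int> ev_in;
  RNGScope rng;
  for (long k = 0; k < n_steps; ++k) {
    if (refr > 0) { refr--; V = V_reset; }
    else V = v_inf + (V - v_inf) * Em + fe * g;
    g *= Ee;
    bool spk = false;
    if (refr == 0 && V >= V_thres) {
      V = V_reset; refr = refr_steps; spk = true; n_spk++;
    }
    // input events this step
    int K = (int)R::rpois(lam);
    ev_in.clear();
    for (int q = 0; q < K; ++q) {
      double r = unif_rand() * tot;
      int lo = 0, hi = ns - 1;
      while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] > r) hi = mid; else lo = mid + 1; }
      ev_in.push_back(lo);
    }
    // STDP: post bump -> depression on pre -> potentiation on post -> pre bump
    if (spk) { x_post *= std::pow(dec_minus, (double)(k - x_post_step)); x_post_step = k; x_post += 1.0; }
    for (int i : ev_in) {
      double xp = x_post * std::pow(dec_minus, (double)(k - x_post_step));
      double nw = w[i] - a_minus * xp;
      w[i] = nw < 0 ? 0 : nw;
    }
    if (spk) {
      for (int i = 0; i < ns; ++i) {
        if (x_pre[i] > 0) {
          x_pre[i] *= std::pow(dec_plus, (double)(k - x_step[i]));
          x_step[i] = k;
          double nw = w[i] + a_plus * x_pre[i];
          w[i] = nw > w_max ? w_max : nw;
        }
      }
    }
    for (int i : ev_in) {
      x_pre[i] *= std::pow(dec_plus, (double)(k - x_step[i]));
      x_step[i] = k;
      x_pre[i] += 1.0;
      g += w[i]; // delivery (affects next step)
    }
    if (norm_every > 0 && (k + 1) % norm_every == 0) {
      double s = 0;
      for (int i = 0; i < ns; ++i) s += w[i];
      if (s > 0) {
        double f = ns * norm_target / s;
        for (int i = 0; i < ns; ++i) {
          double nw = w[i] * f;
          w[i] = nw > w_max ? w_max : nw;
        }
      }
    }
    if (rec_every > 0 && (k + 1) % rec_every == 0) {
      traj.push_back((k + 1) * dt / 1000.0);
      for (int i = 0; i < ns; ++i) traj.push_back(w[i]);
    }
  }
  int nrow = rec_every > 0 ? (int)(traj.size() / (ns + 1)) : 0;
  NumericMatrix tm(nrow, ns + 1);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c <= ns; ++c) tm(r, c) = traj[(size_t)r * (ns + 1) + c];
  return List::create(_["w_final"] = NumericVector(w.begin(), w.end()),
                      _["post_rate"] = n_spk / duration_s,
                      _["trajectory"] = tm);
}
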