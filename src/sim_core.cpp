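#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Full coupled update loop for one trial: LIF membranes, delayed synaptic
// drives, global inhibitory feedback, wavefield noise modulation, STDP
// eligibility traces and dopamine-gated weight updates.
//
// All delays are exact multiples of dt (ring-buffer semantics). Linear decays
// (h, h_ext, h_inh, fbar, c, D_p) use the exact per-step factor exp(-dt/tau);
// v and psi, which carry state-dependent drive, use forward Euler(-Maruyama).
// Gaussian draws come from R's RNG, one per neuron per step in index order,
// so trials are bit-reproducible from set.seed() and a pure-R stepper can
// replay the identical noise sequence.
//
// Update order within a step at time t = k*dt:
//   1. wavefield: influx crossings, psi Euler step (delayed coupling), sigma
//   2. drives: h, h_ext, h_inh decay + delayed spike arrivals + pulses
//   3. membranes: Euler-Maruyama, threshold crossing, reset
//   4. plasticity traces: fbar decay, eligibility decay, STDP events (using
//      pre-increment fbar for all spikes of the step), fbar += 1, clip c
//   5. dopamine: D_p decay, queued phasic arrivals, target-spike jumps
//      enqueued at t + t_p, D_t = d_t * novelty
//   6. weights: S += c*(D_t+D_p)*dt/tau_s unless (c < 0 and D_p < 0), clip

static inline double getd(const List& par, const char* nm) {
  return as<double>(par[nm]);
}

// [[Rcpp::export]]
List sim_trial_cpp(int n,
                   IntegerVector pre,  // 0-based presynaptic index per edge
                   IntegerVector post, // 0-based postsynaptic index per edge
                   NumericVector S_in,
                   NumericVector c_in,
                   NumericVector fbar_in,
                   List par,
                   IntegerVector stim_ids,   // 0-based
                   IntegerVector target_ids, // 0-based
                   IntegerVector false_ids,  // 0-based
                   int task,
                   bool wave, bool tonic, bool phasic, bool plastic,
                   double sigma_const,
                   double d_t_eff, double d_p_eff,
                   double novelty,
                   double duration_ms,
                   int record_every = 0) {
  const int m = pre.size();
  if (post.size() != m || S_in.size() != m || c_in.size() != m)
    stop("edge arrays have inconsistent lengths");

  const double dt      = getd(par, "dt");
  const double v0      = getd(par, "v0");
  const double vth     = getd(par, "v_th");
  const double vreset  = getd(par, "v_reset");
  const double tau_m   = getd(par, "tau_m");
  const double tau_h   = getd(par, "tau_h");
  const double h0      = getd(par, "h0");
  const double t_d     = getd(par, "t_d");
  const double tau_inh = getd(par, "tau_inh");
  const double t_h     = getd(par, "t_h");
  const double beta    = getd(par, "beta");
  const double t_on    = getd(par, "t_on");
  const double t_off   = getd(par, "t_off");
  const double period  = getd(par, "pulse_period");
  const double amp     = getd(par, "pulse_amplitude");
  const double S_max   = getd(par, "S_max");
  const double gamma   = getd(par, "gamma");
  const double ltd     = getd(par, "ltd_factor");
  const double tau_stdp= getd(par, "tau_stdp");
  const double tau_c   = getd(par, "tau_c");
  const double tau_s   = getd(par, "tau_s");
  const double tau_p   = getd(par, "tau_p");
  const double t_p     = getd(par, "t_p");
  const double tau_d   = getd(par, "tau_d");
  const double dp_bound= getd(par, "dp_bound");
  const double tau_w   = getd(par, "tau_w");
  const double delta_t = getd(par, "delta_t");
  const double theta   = getd(par, "theta");
  const double eta     = getd(par, "eta");
  const double kap_in  = getd(par, "kappa_in");
  const double kap_out = getd(par, "kappa_out");
  const double psi_min = getd(par, "psi_min");
  const double psi_max = getd(par, "psi_max");
  const double sig_base= getd(par, "sigma_base");
  const double sig_min = getd(par, "sigma_min");
  const double sig_max = getd(par, "sigma_max");
  const double g_post  = getd(par, "g_post");   // field drive after t_off
  const double ngain   = getd(par, "noise_gain");

  const int nsteps   = (int) std::lround(duration_ms / dt);
  const int td_steps = (int) std::lround(t_d / dt);
  const int th_steps = (int) std::lround(t_h / dt);
  const int tp_steps = (int) std::lround(t_p / dt);
  const int dl_steps = (int) std::lround(delta_t / dt); // wavefield delay
  const int per_steps= (int) std::lround(period / dt);
  const int on_step  = (int) std::lround(t_on / dt);
  const int off_step = (int) std::lround(t_off / dt);

  const double dec_h   = std::exp(-dt / tau_h);
  const double dec_inh = std::exp(-dt / tau_inh);
  const double dec_fb  = std::exp(-dt / tau_stdp);
  const double dec_c   = std::exp(-dt / tau_c);
  const double dec_p   = std::exp(-dt / tau_p);
  const double sqdt    = std::sqrt(dt);
  const double c_bound = S_max / 2.0;

  // CSR adjacency by presynaptic and by postsynaptic neuron
  std::vector<int> out_start(n + 1, 0), in_start(n + 1, 0);
  for (int e = 0; e < m; ++e) { out_start[pre[e] + 1]++; in_start[post[e] + 1]++; }
  for (int i = 0; i < n; ++i) { out_start[i + 1] += out_start[i]; in_start[i + 1] += in_start[i]; }
  std::vector<int> out_edge(m), in_edge(m), ofill(out_start.begin(), out_start.end() - 1),
                   ifill(in_start.begin(), in_start.end() - 1);
  for (int e = 0; e < m; ++e) {
    out_edge[ofill[pre[e]]++] = e;
    in_edge[ifill[post[e]]++] = e;
  }

  std::vector<double> S(S_in.begin(), S_in.end());
  std::vector<double> cc(c_in.begin(), c_in.end());
  std::vector<double> fbar(fbar_in.begin(), fbar_in.end());
  std::vector<double> v(n, v0), h(n, 0.0), hext(n, 0.0), sigma(n, wave ? sig_base : sigma_const);
  double hinh = 0.0;

  std::vector<char> is_stim(n, 0), is_target(n, 0), is_false(n, 0);
  std::vector<int> false_pos(n, -1);
  for (int i = 0; i < stim_ids.size(); ++i) is_stim[stim_ids[i]] = 1;
  for (int i = 0; i < target_ids.size(); ++i) is_target[target_ids[i]] = 1;
  std::vector<int> nfalse(false_ids.size(), 0);
  for (int i = 0; i < false_ids.size(); ++i) { is_false[false_ids[i]] = 1; false_pos[false_ids[i]] = i; }
  int ntrue = 0;

  // wavefield state
  std::vector<double> psi, g;
  std::vector<char> crossed; // per edge: neighbor already counted this trial
  std::vector<int> cross_n;  // per neuron: number of distinct inflow neighbors
  std::vector<double> psi_hist; // ring buffer n * dl_steps, column-major by step
  if (wave) {
    psi.assign(n, 0.0); g.assign(n, 0.0);
    crossed.assign(m, 0); cross_n.assign(n, 0);
    psi_hist.assign((size_t) n * dl_steps, 0.0);
  }

  std::vector<int> spike_step, spike_id;
  spike_step.reserve(4096); spike_id.reserve(4096);
  size_t p_syn = 0, p_inh = 0; // delayed-consumption pointers into spike list

  // pending phasic dopamine jumps (arrival step is nondecreasing)
  std::vector<int> pend_step; std::vector<double> pend_amt;
  size_t p_pend = 0;
  double Dp = 0.0;
  double Dt = tonic ? d_t_eff * novelty : 0.0;

  double R_now = 0.0, R_end = 0.0;
  double latency = NA_REAL;

  const int nrec = (record_every > 0) ? nsteps / record_every : 0;
  NumericMatrix rec_psi = (nrec > 0 && wave) ? NumericMatrix(nrec, n) : NumericMatrix(0, 0);
  NumericMatrix rec_sigma = (nrec > 0) ? NumericMatrix(nrec, n) : NumericMatrix(0, 0);
  NumericVector rec_Dp = (nrec > 0) ? NumericVector(nrec) : NumericVector(0);
  NumericVector rec_t  = (nrec > 0) ? NumericVector(nrec) : NumericVector(0);
  int irec = 0;

  RNGScope scope;

  for (int k = 0; k < nsteps; ++k) {
    const double t = k * dt;

    // ---- 1. wavefield -------------------------------------------------
    if (wave) {
      const int hcol = k % dl_steps;                 // slot to overwrite
      const int dcol = hcol;                         // k - dl_steps lives here
      const bool have_delay = k >= dl_steps;
      // field drive g(t): staircase during stimulation, g_post after
      if (k >= on_step && k < off_step) {
        if ((k - on_step) % per_steps == 0)
          for (int i = 0; i < stim_ids.size(); ++i) g[stim_ids[i]] += eta;
      } else if (k == off_step) {
        for (int i = 0; i < stim_ids.size(); ++i) g[stim_ids[i]] = g_post;
      }
      // coupling + influx counting use psi at t (pre-update) and psi(t - delta_t)
      std::vector<double> dpsi(n, 0.0);
      for (int e = 0; e < m; ++e) {
        const int j = pre[e], i = post[e];
        const double pj_del = have_delay ? psi_hist[(size_t) dcol * n + j] : 0.0;
        // the rectified gap [psi_j(t - delta_t) - psi_i(t) - theta]_+ of edge
        // j -> i feeds the postsynaptic field (inflow) and drains the
        // presynaptic one (outflow)
        const double w = pj_del - psi[i] - theta;
        if (w > 0) {
          dpsi[i] += kap_in * w;
          dpsi[j] -= kap_out * w;
          if (!crossed[e]) { crossed[e] = 1; cross_n[i]++; }
        }
      }
      for (int i = 0; i < n; ++i) {
        psi_hist[(size_t) hcol * n + i] = psi[i];     // store psi at step k
        double p = psi[i] + dt * ((g[i] - psi[i]) / tau_w + dpsi[i]);
        if (p < psi_min) p = psi_min; else if (p > psi_max) p = psi_max;
        psi[i] = p;
        const double alpha = 5.0 * std::tanh((double) cross_n[i]);
        double s = alpha * p + sig_base;
        if (s < sig_min) s = sig_min; else if (s > sig_max) s = sig_max;
        sigma[i] = s;
      }
    }

    // ---- 2. synaptic drives, external input, inhibition ----------------
    int n_delayed_inh = 0;
    while (p_inh < spike_step.size() && spike_step[p_inh] == k - th_steps) { n_delayed_inh++; p_inh++; }
    hinh = hinh * dec_inh + beta * n_delayed_inh;

    for (int i = 0; i < n; ++i) { h[i] *= dec_h; hext[i] *= dec_h; }
    while (p_syn < spike_step.size() && spike_step[p_syn] == k - td_steps) {
      const int j = spike_id[p_syn];
      for (int q = out_start[j]; q < out_start[j + 1]; ++q) {
        const int e = out_edge[q];
        h[post[e]] += h0 * S[e];
      }
      p_syn++;
    }
    if (k >= on_step && k < off_step && (k - on_step) % per_steps == 0)
      for (int i = 0; i < stim_ids.size(); ++i) hext[stim_ids[i]] += amp;

    // ---- 3. membrane Euler-Maruyama step -------------------------------
    const int spk_from = (int) spike_step.size();
    for (int i = 0; i < n; ++i) {
      const double xi = norm_rand();
      v[i] += dt * (v0 - v[i] + h[i] + hext[i] - hinh) / tau_m
              + ngain * sigma[i] * sqdt * xi;
      if (v[i] >= vth) {
        v[i] = vreset;
        spike_step.push_back(k);
        spike_id.push_back(i);
      }
    }
    const int spk_to = (int) spike_step.size();

    // ---- 4. plasticity traces ------------------------------------------
    if (plastic) {
      for (int i = 0; i < n; ++i) fbar[i] *= dec_fb;
      for (int e = 0; e < m; ++e) cc[e] *= dec_c;
      if (spk_to > spk_from) {
        // STDP increments with pre-jump fbar of all of this step's spikes
        for (int s = spk_from; s < spk_to; ++s) {
          const int i = spike_id[s];
          for (int q = in_start[i]; q < in_start[i + 1]; ++q) {  // i as post
            const int e = in_edge[q];
            cc[e] += gamma * fbar[pre[e]];
          }
          for (int q = out_start[i]; q < out_start[i + 1]; ++q) { // i as pre
            const int e = out_edge[q];
            cc[e] -= ltd * gamma * fbar[post[e]];
          }
        }
        for (int s = spk_from; s < spk_to; ++s) fbar[spike_id[s]] += 1.0;
        for (int e = 0; e < m; ++e) {
          if (cc[e] > c_bound) cc[e] = c_bound;
          else if (cc[e] < -c_bound) cc[e] = -c_bound;
        }
      }
    }

    // ---- 5. dopamine ---------------------------------------------------
    Dp *= dec_p;
    bool dirty = false;
    while (p_pend < pend_step.size() && pend_step[p_pend] <= k) {
      Dp += pend_amt[p_pend]; p_pend++; dirty = true;
    }
    for (int s = spk_from; s < spk_to; ++s) {
      const int i = spike_id[s];
      if (!is_target[i] && !is_false[i]) continue;
      if (is_target[i]) ntrue++; else nfalse[false_pos[i]]++;
      if (is_target[i] && ISNA(latency)) latency = t - t_on;
      // reward on counts including this spike
      int maxf = 0, sumf = 0;
      for (size_t q = 0; q < nfalse.size(); ++q) { sumf += nfalse[q]; if (nfalse[q] > maxf) maxf = nfalse[q]; }
      if (task == 1) R_now = (ntrue + sumf > 5) ? (-0.5 + 1.5 * (ntrue > maxf)) : 0.0;
      else if (task == 2) R_now = (ntrue > 0) ? 1.0 : 0.0;
      else R_now = (double) (ntrue >= maxf + 5) - (double) (maxf >= ntrue + 5);
      if (phasic) {
        double gam_R = 0.0;
        if (t > t_on) gam_R = (t <= t_off) ? d_p_eff : d_p_eff * std::exp(-(t - t_off) / tau_d);
        const double inc = R_now * gam_R * novelty;
        if (inc != 0.0) { pend_step.push_back(k + tp_steps); pend_amt.push_back(inc); }
      }
    }
    if (dirty) {
      if (Dp > dp_bound) Dp = dp_bound; else if (Dp < -dp_bound) Dp = -dp_bound;
    }

    // ---- 6. weight update ----------------------------------------------
    if (plastic && (Dt != 0.0 || Dp != 0.0)) {
      const double fac = (Dt + Dp) * dt / tau_s;
      for (int e = 0; e < m; ++e) {
        if (cc[e] < 0 && Dp < 0) continue;  // frozen corner of the rule
        double s = S[e] + cc[e] * fac;
        if (s < 0) s = 0; else if (s > S_max) s = S_max;
        S[e] = s;
      }
    }

    if (nrec > 0 && (k + 1) % record_every == 0 && irec < nrec) {
      for (int i = 0; i < n; ++i) {
        if (wave) rec_psi(irec, i) = psi[i];
        rec_sigma(irec, i) = sigma[i];
      }
      rec_Dp[irec] = Dp;
      rec_t[irec] = t;
      irec++;
    }

    if ((k & 0x3FF) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(v[i]) || !std::isfinite(h[i]))
          stop("non-finite membrane state at neuron %d, t = %.1f ms", i + 1, t);
    }
  }

  R_end = R_now;

  List out = List::create(
    _["spike_step"] = wrap(spike_step),
    _["spike_id"]   = wrap(spike_id),
    _["S"]          = wrap(S),
    _["c"]          = wrap(cc),
    _["fbar"]       = wrap(fbar),
    _["n_true"]     = ntrue,
    _["n_false"]    = wrap(nfalse),
    _["R_end"]      = R_end,
    _["Dp_end"]     = Dp,
    _["latency_ms"] = latency,
    _["v"]          = wrap(v));
  if (nrec > 0) {
    out["rec_t"] = rec_t;
    out["rec_sigma"] = rec_sigma;
    out["rec_Dp"] = rec_Dp;
    if (wave) out["rec_psi"] = rec_psi;
  }
  return out;
}
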