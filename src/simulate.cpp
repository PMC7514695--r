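#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Time-stepped (1 ms) simulation of the grouped Izhikevich network with
// delayed current-based deliveries, tonic input and additive pair STDP.
//
// Integration scheme: two 0.5 ms forward-Euler half-steps for v, one 1 ms
// step for u, spike detection on the 1 ms grid (v >= 30 mV), v reset to c
// and u incremented by d at a spike. Delivered input at time t is the sum
// of the weights of all spikes arriving (spike time + delay == t).
//
// STDP bookkeeping uses last-spike times: when a spike arrives at a target
// that fired dt ms earlier, the synapse derivative is depressed by
// a_minus*exp(-dt/tau); when a neuron fires, each plastic afferent whose
// last spike arrived dt ms earlier is potentiated by a_plus*exp(-dt/tau).
// Once per simulated second (within the plasticity window) the derivative
// is flushed into the weight: w <- clip(w + bias + sd, 0, w_upper),
// sd <- decay*sd.
//
// Hot loops run on plain C++ arrays; the R vectors are copied on entry.
//
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector a, NumericVector b, NumericVector c_,
              NumericVector d, NumericVector v0, NumericVector u0,
              IntegerVector group, LogicalVector is_exc,
              IntegerVector pre, IntegerVector post,
              NumericVector weight0, IntegerVector delay,
              LogicalVector plastic,
              int n_groups, int t_total_ms, int t_tonic_ms, int t_stdp_ms,
              double tonic_current, int tonic_per_group,
              bool stdp_enabled,
              double a_plus, double a_minus, double tau,
              double flush_bias, double flush_decay, double w_upper,
              int lap_from_ms, int spikes_from_ms) {
  const int n = a.size();
  const int ns = pre.size();

  std::vector<double> pa(a.begin(), a.end()), pb(b.begin(), b.end()),
      pc(c_.begin(), c_.end()), pd(d.begin(), d.end());
  std::vector<int> ppre(pre.begin(), pre.end()),
      ppost(post.begin(), post.end()), pdelay(delay.begin(), delay.end());
  std::vector<char> pplastic(plastic.begin(), plastic.end());

  // CSR over outgoing synapses (neuron ids are 1-based on the R side)
  std::vector<int> out_start(n + 1, 0);
  for (int s = 0; s < ns; ++s) out_start[ppre[s]] += 1;
  for (int i = 0; i < n; ++i) out_start[i + 1] += out_start[i];
  std::vector<int> out_sidx(ns);
  {
    std::vector<int> fill(out_start.begin(), out_start.end() - 1);
    for (int s = 0; s < ns; ++s) out_sidx[fill[ppre[s] - 1]++] = s;
  }

  // CSR over plastic incoming synapses (for potentiation at post spike)
  std::vector<int> in_start(n + 1, 0), in_sidx;
  {
    std::vector<int> cnt(n, 0);
    int np = 0;
    for (int s = 0; s < ns; ++s)
      if (pplastic[s]) { cnt[ppost[s] - 1] += 1; ++np; }
    in_sidx.resize(np);
    for (int i = 0; i < n; ++i) in_start[i + 1] = in_start[i] + cnt[i];
    std::vector<int> fill(in_start.begin(), in_start.end() - 1);
    for (int s = 0; s < ns; ++s)
      if (pplastic[s]) in_sidx[fill[ppost[s] - 1]++] = s;
  }

  int max_delay = 1;
  for (int s = 0; s < ns; ++s) {
    if (pdelay[s] < 1) stop("synaptic delays must be >= 1 ms");
    if (pdelay[s] > max_delay) max_delay = pdelay[s];
  }
  const int nslot = max_delay + 1;

  // group membership (0-based), excitatory members per group for the LAP
  std::vector<std::vector<int>> members(n_groups), exc_members(n_groups);
  for (int i = 0; i < n; ++i) {
    int g = group[i] - 1;
    if (g < 0 || g >= n_groups) stop("neuron group id out of range");
    members[g].push_back(i);
    if (is_exc[i]) exc_members[g].push_back(i);
  }
  for (int g = 0; g < n_groups; ++g)
    if (exc_members[g].empty()) stop("every group needs excitatory neurons");

  // arrival event lists per ring slot: synapse indices landing at that ms
  std::vector<std::vector<int>> arrivals(nslot);

  std::vector<double> v(v0.begin(), v0.end()), u(u0.begin(), u0.end());
  std::vector<double> w(weight0.begin(), weight0.end());
  std::vector<double> sd(ns, 0.0);
  std::vector<double> I(n, 0.0);
  std::vector<int> lastfire(n, -1000000);

  // exponential pairing window, tabulated per ms out to 10 tau
  const int wlen = (int)std::ceil(10.0 * tau);
  std::vector<double> expw(wlen + 1);
  for (int t = 0; t <= wlen; ++t) expw[t] = std::exp(-t / tau);

  const int lap_cols = t_total_ms - lap_from_ms;
  NumericMatrix lap(lap_cols > 0 ? n_groups : 0,
                    lap_cols > 0 ? lap_cols : 0);
  double* lap_ptr = lap_cols > 0 ? REAL(lap) : nullptr;
  std::vector<int> spike_t, spike_id;
  std::vector<int> fired;
  fired.reserve(n);

  double* vp = v.data();
  double* up = u.data();
  double* Ip = I.data();
  double* wp = w.data();
  double* sdp = sd.data();
  int* lfp = lastfire.data();

  NumericVector w_post_stdp(ns);
  bool snapped = false;
  // extremes of the plastic weights observed right after each flush
  double flush_wmin = R_PosInf, flush_wmax = R_NegInf;
  int n_flushes = 0;

  for (int t = 0; t < t_total_ms; ++t) {
    const int slot = t % nslot;
    const bool stdp_now = stdp_enabled && t < t_stdp_ms;

    // deliveries arriving this millisecond (+ depression of the synapse)
    std::fill(I.begin(), I.end(), 0.0);
    for (int s : arrivals[slot]) {
      const int j = ppost[s] - 1;
      Ip[j] += wp[s];
      if (stdp_now && pplastic[s]) {
        const int dt = t - lfp[j];
        if (dt >= 0 && dt <= wlen) sdp[s] -= a_minus * expw[dt];
      }
    }
    arrivals[slot].clear();

    // tonic drive: a few random neurons per group, during the input window
    if (t < t_tonic_ms && tonic_per_group > 0) {
      for (int g = 0; g < n_groups; ++g) {
        const int sz = (int)members[g].size();
        for (int rdraw = 0; rdraw < tonic_per_group; ++rdraw) {
          int idx = (int)(unif_rand() * sz);
          if (idx >= sz) idx = sz - 1;
          Ip[members[g][idx]] += tonic_current;
        }
      }
    }

    // membrane update: two half-steps for v, one step for u
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double vi = vp[i];
      const double ui = up[i];
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ip[i]);
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ip[i]);
      vp[i] = vi;
      up[i] = ui + pa[i] * (pb[i] * vi - ui);
      bad |= !std::isfinite(vi);
    }
    if (bad) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(vp[i]) || !std::isfinite(up[i]))
          stop("numerical divergence at neuron %d, t = %d ms", i + 1, t);
    }

    // spike detection (before reset, so the LAP sees the capped peak)
    fired.clear();
    for (int i = 0; i < n; ++i)
      if (vp[i] >= 30.0) fired.push_back(i);

    if (t >= lap_from_ms) {
      double* col = lap_ptr + (size_t)(t - lap_from_ms) * n_groups;
      for (int g = 0; g < n_groups; ++g) {
        double acc = 0.0;
        for (int i : exc_members[g]) acc += (vp[i] > 30.0) ? 30.0 : vp[i];
        col[g] = acc / exc_members[g].size();
      }
    }

    for (int i : fired) {
      if (t >= spikes_from_ms) {
        spike_t.push_back(t);
        spike_id.push_back(i + 1);
      }
      // potentiate plastic afferents: pre spike arrived before this spike
      if (stdp_now) {
        for (int p = in_start[i]; p < in_start[i + 1]; ++p) {
          const int s = in_sidx[p];
          const int dt = t - (lfp[ppre[s] - 1] + pdelay[s]);
          if (dt >= 0 && dt <= wlen) sdp[s] += a_plus * expw[dt];
        }
      }
      vp[i] = pc[i];
      up[i] += pd[i];
      // schedule deliveries
      for (int p = out_start[i]; p < out_start[i + 1]; ++p) {
        const int s = out_sidx[p];
        arrivals[(t + pdelay[s]) % nslot].push_back(s);
      }
    }
    for (int i : fired) lfp[i] = t;

    // per-second weight flush, within the plasticity window only
    if (stdp_enabled && (t + 1) % 1000 == 0 && t < t_stdp_ms) {
      for (int s = 0; s < ns; ++s) {
        if (!pplastic[s]) continue;
        double nw = wp[s] + flush_bias + sdp[s];
        if (nw < 0.0) nw = 0.0;
        if (nw > w_upper) nw = w_upper;
        wp[s] = nw;
        sdp[s] *= flush_decay;
        if (nw < flush_wmin) flush_wmin = nw;
        if (nw > flush_wmax) flush_wmax = nw;
      }
      ++n_flushes;
    }
    if (!snapped && t + 1 >= t_stdp_ms) {
      for (int s = 0; s < ns; ++s) w_post_stdp[s] = wp[s];
      snapped = true;
    }
  }
  if (!snapped)
    for (int s = 0; s < ns; ++s) w_post_stdp[s] = wp[s];

  return List::create(
    _["spike_t"] = IntegerVector(spike_t.begin(), spike_t.end()),
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["lap"] = lap,
    _["lap_from_ms"] = lap_from_ms,
    _["weights_post_stdp"] = w_post_stdp,
    _["weights_final"] = NumericVector(w.begin(), w.end()),
    _["flush_weight_range"] = NumericVector::create(flush_wmin, flush_wmax),
    _["n_flushes"] = n_flushes
  );
}
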