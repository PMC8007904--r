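#include <Rcpp.h>
using namespace Rcpp;

// Izhikevich two-variable neuron network with delayed synapses and additive
// STDP on excitatory weights.  Fixed-step 1 ms integration, membrane potential
// advanced in two 0.5 ms half-steps for numerical stability.
//
// All randomness is drawn from R's RNG so that set.seed() in R controls the
// simulation completely.
//
// Arguments (0-based neuron indices):
//   exc        logical, TRUE for excitatory neurons
//   pre/post   synapse endpoints
//   weight     initial synaptic weights (negative for inhibitory)
//   delay_ms   integer conduction delays, >= 1
//   recipient  logical, neuron receives the random external input
//   a, d       per-neuron recovery parameters (b = 0.2, c = -65 fixed)
//   n_ms       simulated milliseconds
//   input_strength  amplitude of the external current pulse (mV-equivalent)
//   input_rate      probability of one external event per 1 ms step
//   s_max      upper clip for excitatory weights
//   stdp       enable plasticity
// [[Rcpp::export]]
List cpp_simulate(int n,
                  LogicalVector exc,
                  IntegerVector pre,
                  IntegerVector post,
                  NumericVector weight,
                  IntegerVector delay_ms,
                  LogicalVector recipient,
                  NumericVector a,
                  NumericVector d,
                  int n_ms,
                  double input_strength,
                  double input_rate,
                  double s_max,
                  bool stdp) {
  const int ns = pre.size();
  const double b = 0.2, c = -65.0;
  const double trace_decay = std::exp(-1.0 / 20.0);  // tau = 20 ms

  std::vector<double> v(n, -65.0), u(n);
  for (int i = 0; i < n; ++i) u[i] = b * v[i];

  std::vector<double> w(weight.begin(), weight.end());
  std::vector<double> sd(ns, 0.0);        // STDP eligibility derivative
  std::vector<double> arr_trace(ns, 0.0); // presynaptic-arrival trace
  std::vector<double> post_trace(n, 0.0); // postsynaptic-spike trace

  // incoming / outgoing synapse index lists
  std::vector<std::vector<int> > in_syn(n), out_syn(n);
  int max_delay = 1;
  for (int s = 0; s < ns; ++s) {
    in_syn[post[s]].push_back(s);
    out_syn[pre[s]].push_back(s);
    if (delay_ms[s] > max_delay) max_delay = delay_ms[s];
  }
  const int ring_n = max_delay + 1;
  std::vector<std::vector<int> > ring(ring_n);

  std::vector<double> I(n);
  std::vector<int> fired;
  std::vector<int> spike_unit, spike_ms;
  spike_unit.reserve(n_ms / 4);
  spike_ms.reserve(n_ms / 4);

  std::vector<int> recip_ids;
  for (int i = 0; i < n; ++i) if (recipient[i]) recip_ids.push_back(i);

  RNGScope scope;

  for (int t = 0; t < n_ms; ++t) {
    // trace decay
    for (int s = 0; s < ns; ++s) arr_trace[s] *= trace_decay;
    for (int i = 0; i < n; ++i) post_trace[i] *= trace_decay;

    std::fill(I.begin(), I.end(), 0.0);

    // external input: with prob input_rate one uniformly chosen recipient
    // receives a current pulse
    if (!recip_ids.empty() && unif_rand() < input_rate) {
      int k = (int)(unif_rand() * recip_ids.size());
      if (k >= (int)recip_ids.size()) k = recip_ids.size() - 1;
      I[recip_ids[k]] += input_strength;
    }

    // deliver spikes arriving now
    std::vector<int> &arriving = ring[t % ring_n];
    for (size_t j = 0; j < arriving.size(); ++j) {
      int s = arriving[j];
      I[post[s]] += w[s];
      if (exc[pre[s]]) {
        sd[s] -= post_trace[post[s]];   // pre after post: depression
        arr_trace[s] = 0.1;             // remember arrival for potentiation
      }
    }
    arriving.clear();

    // membrane integration
    for (int i = 0; i < n; ++i) {
      double vi = v[i], ui = u[i];
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
      ui += a[i] * (b * vi - ui);
      if (vi < -100.0) vi = -100.0;     // divergence guard
      v[i] = vi;
      u[i] = ui;
    }

    // threshold crossings
    fired.clear();
    for (int i = 0; i < n; ++i) {
      if (v[i] >= 30.0) {
        fired.push_back(i);
        v[i] = c;
        u[i] += d[i];
      }
    }
    for (size_t j = 0; j < fired.size(); ++j) {
      int i = fired[j];
      spike_unit.push_back(i);
      spike_ms.push_back(t);
      post_trace[i] = 0.12;
      // potentiate incoming excitatory synapses whose spikes arrived before
      const std::vector<int> &isy = in_syn[i];
      for (size_t k = 0; k < isy.size(); ++k) {
        int s = isy[k];
        if (exc[pre[s]]) sd[s] += arr_trace[s];
      }
      // schedule outgoing arrivals
      const std::vector<int> &osy = out_syn[i];
      for (size_t k = 0; k < osy.size(); ++k) {
        int s = osy[k];
        ring[(t + delay_ms[s]) % ring_n].push_back(s);
      }
    }

    // once-per-second weight update
    if (stdp && (t % 1000 == 999)) {
      for (int s = 0; s < ns; ++s) {
        if (!exc[pre[s]]) continue;
        double ws = w[s] + 0.01 + sd[s];
        if (ws < 0.0) ws = 0.0;
        if (ws > s_max) ws = s_max;
        w[s] = ws;
        sd[s] *= 0.9;
      }
    }
  }

  return List::create(_["spike_unit"] = wrap(spike_unit),
                      _["spike_ms"] = wrap(spike_ms),
                      _["weights"] = wrap(w));
}
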