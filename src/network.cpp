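#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time leaky integrate-and-fire network, one synaptic delay slot
// per `delay_bins`.  Connectivity is passed in compressed sparse row form
// over *sources*: neuron j projects to targets targ_idx[targ_ptr[j] ..
// targ_ptr[j+1]-1] with weights targ_w (mV).  All times are in integration
// bins; the membrane decays by `leak` per bin.  Spikes can be forced three
// ways: a stimulation pulse (stim_neurons at bin t_stim), independent
// Bernoulli(p_spont) spontaneous firing, and a correlated drive that each
// bin forces drive_counts[t] members of drive_pool to fire.  Forced spikes
// override the refractory state, mirroring direct activation.
//
// Returns per-bin population counts, total spike count, and (optionally)
// the full binary raster.
// [[Rcpp::export]]
List cpp_simulate_lif(IntegerVector targ_ptr, IntegerVector targ_idx,
                      NumericVector targ_w, int n_neurons, int n_bins,
                      double leak, double v_thresh, double v_reset,
                      int ref_bins, int delay_bins,
                      IntegerVector stim_neurons, int t_stim,
                      double p_spont, IntegerVector drive_counts,
                      IntegerVector drive_pool, bool return_raster,
                      double v_init_max) {
  // Membranes start uniformly distributed below threshold (the residue
  // of prior background drive).  This keeps pulse propagation graded: a
  // synaptic volley delivering mu mV recruits about a fraction mu/theta
  // of its targets, so a pulse of A spikes produces A * sigma
  // descendants rather than an all-or-none response.
  std::vector<double> v(n_neurons, 0.0);
  if (v_init_max > 0.0)
    for (int i = 0; i < n_neurons; ++i) v[i] = v_init_max * unif_rand();
  std::vector<int> refr(n_neurons, 0);
  int n_slots = delay_bins + 1;
  // circular buffer of future synaptic input
  std::vector<std::vector<double>> inbuf(n_slots,
                                         std::vector<double>(n_neurons, 0.0));
  IntegerVector counts(n_bins);
  IntegerMatrix raster;
  if (return_raster) raster = IntegerMatrix(n_neurons, n_bins);

  std::vector<int> spikers;
  spikers.reserve(n_neurons);
  std::vector<char> fired(n_neurons, 0);
  std::vector<int> pool(drive_pool.begin(), drive_pool.end());
  bool has_drive = drive_counts.size() > 0 && pool.size() > 0;
  double total_spikes = 0.0;

  for (int t = 0; t < n_bins; ++t) {
    int slot = t % n_slots;
    std::vector<double> &I = inbuf[slot];
    spikers.clear();

    // integrate and threshold
    for (int i = 0; i < n_neurons; ++i) {
      fired[i] = 0;
      if (refr[i] > 0) {
        refr[i]--;
      } else {
        v[i] = v[i] * leak + I[i];
        if (v[i] >= v_thresh) fired[i] = 1;
      }
      I[i] = 0.0;
    }

    // forced spikes: stimulation pulse
    if (t == t_stim) {
      for (int k = 0; k < stim_neurons.size(); ++k) fired[stim_neurons[k]] = 1;
    }
    // forced spikes: uncorrelated spontaneous firing
    if (p_spont > 0.0) {
      for (int i = 0; i < n_neurons; ++i)
        if (unif_rand() < p_spont) fired[i] = 1;
    }
    // forced spikes: correlated drive, k_t distinct neurons from the pool
    if (has_drive && t < drive_counts.size()) {
      int k = drive_counts[t];
      int m = (int)pool.size();
      if (k > m) k = m;
      // partial Fisher-Yates over the pool
      for (int j = 0; j < k; ++j) {
        int r = j + (int)(unif_rand() * (m - j));
        if (r >= m) r = m - 1;
        std::swap(pool[j], pool[r]);
        fired[pool[j]] = 1;
      }
    }

    for (int i = 0; i < n_neurons; ++i) {
      if (!fired[i]) continue;
      spikers.push_back(i);
      v[i] = v_reset;
      refr[i] = ref_bins;
    }

    counts[t] = (int)spikers.size();
    total_spikes += counts[t];
    if (return_raster)
      for (size_t s = 0; s < spikers.size(); ++s) raster(spikers[s], t) = 1;

    // deliver synaptic output after the delay
    int dslot = (t + delay_bins) % n_slots;
    std::vector<double> &out = inbuf[dslot];
    for (size_t s = 0; s < spikers.size(); ++s) {
      int j = spikers[s];
      for (int e = targ_ptr[j]; e < targ_ptr[j + 1]; ++e)
        out[targ_idx[e]] += targ_w[e];
    }
  }

  List res = List::create(_["counts"] = counts,
                          _["total_spikes"] = total_spikes);
  if (return_raster) res["raster"] = raster;
  return res;
}
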