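#include <Rcpp.h>
using namespace Rcpp;

// Core branching-process update loop.
//
// targets: n_units x out_degree matrix of 0-based target indices
// probs:   n_units x out_degree matrix of transmission probabilities
// Returns an event list (bin, channel), both 0-based.
//
// Update rule per time step t (t = 0 .. n_steps-1):
//   * every unit draws a spontaneous uniform; a non-refractory unit becomes
//     active if the draw <= p_spont;
//   * every unit active at t-1 attempts transmission along each of its
//     outgoing connections (rand <= p_ij); a transmission activates the
//     target only if the target is not refractory; multiple inputs combine
//     by OR;
//   * a unit active at t is refractory during t+1 .. t+refractory_steps.
//
// Uniform draws are made unconditionally (one per unit per step for the
// spontaneous source, one per outgoing connection per active unit) so that
// the draw sequence -- and hence the raster for a given seed -- does not
// depend on incidental ordering of state checks. Uses R's RNG: seed with
// set.seed() before calling.
// [[Rcpp::export]]
List simulate_branching_cpp(IntegerMatrix targets, NumericMatrix probs,
                            int n_steps, double p_spont,
                            int refractory_steps, IntegerVector init_active) {
  const int n = targets.nrow();
  const int k = targets.ncol();

  std::vector<int> refr_until(n, -1);     // last refractory bin per unit
  std::vector<char> prev(n, 0), cur(n, 0);
  std::vector<int> ev_bin, ev_ch;
  ev_bin.reserve(4096);
  ev_ch.reserve(4096);

  RNGScope scope;

  for (int t = 0; t < n_steps; ++t) {
    std::fill(cur.begin(), cur.end(), 0);

    // spontaneous activation
    for (int j = 0; j < n; ++j) {
      double u = unif_rand();
      if (t > refr_until[j] && u <= p_spont) cur[j] = 1;
    }

    // forced initial activity at t = 0
    if (t == 0) {
      for (int m = 0; m < init_active.size(); ++m) {
        int j = init_active[m];
        if (j >= 0 && j < n) cur[j] = 1;
      }
    }

    // driven activation from units active at t-1
    if (t > 0) {
      for (int i = 0; i < n; ++i) {
        if (!prev[i]) continue;
        for (int c = 0; c < k; ++c) {
          double u = unif_rand();
          if (u <= probs(i, c)) {
            int j = targets(i, c);
            if (t > refr_until[j]) cur[j] = 1;
          }
        }
      }
    }

    for (int j = 0; j < n; ++j) {
      if (cur[j]) {
        refr_until[j] = t + refractory_steps;
        ev_bin.push_back(t);
        ev_ch.push_back(j);
      }
    }
    std::swap(prev, cur);
  }

  return List::create(_["bin"] = wrap(ev_bin), _["channel"] = wrap(ev_ch));
}
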