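#include <Rcpp.h>
using namespace Rcpp;

// Cumulative +/-1 walk; optionally reflected (absolute value of the
// cumulative sum).  Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_coin_walk(double n_flips, double p_heads, bool reflect) {
  R_xlen_t n = (R_xlen_t)n_flips;
  NumericVector x(n);
  double pos = 0.0;
  for (R_xlen_t t = 0; t < n; ++t) {
    pos += (unif_rand() < p_heads) ? 1.0 : -1.0;
    x[t] = reflect ? std::fabs(pos) : pos;
  }
  return x;
}

// Stream a reflected +/-1 walk and collect zero-to-zero excursion
// statistics without storing the trace.  An excursion runs from the step
// that leaves the origin to the step that returns to it; its duration is
// the number of flips in that run and its size the sum of the reflected
// heights after each flip (the terminal zero contributes nothing).
// Height profiles (the positive heights only) are accumulated for
// durations up to shape_max_t so average shapes can be formed later.
// A trailing excursion that never returns to zero is discarded.
// [[Rcpp::export]]
List cpp_coin_excursions(double n_flips, double p_heads, int shape_max_t) {
  R_xlen_t n = (R_xlen_t)n_flips;
  std::vector<double> durations, sizes;
  // shape_sums[T][i]: summed height at step i over excursions of duration T
  NumericMatrix shape_sums(shape_max_t + 1, shape_max_t + 1);
  std::vector<double> shape_counts(shape_max_t + 1, 0.0);
  std::vector<double> buf;
  buf.reserve(shape_max_t + 1);

  long long pos = 0;
  double cur_size = 0.0;
  double cur_dur = 0.0;
  for (R_xlen_t t = 0; t < n; ++t) {
    pos += (unif_rand() < p_heads) ? 1 : -1;
    double h = (double)std::llabs(pos);
    cur_dur += 1.0;
    cur_size += h;
    if ((R_xlen_t)buf.size() <= (R_xlen_t)shape_max_t) buf.push_back(h);
    if (pos == 0) {
      durations.push_back(cur_dur);
      sizes.push_back(cur_size);
      if (cur_dur <= shape_max_t) {
        int T = (int)cur_dur;
        for (int i = 0; i < T; ++i) shape_sums(T, i) += buf[i];
        shape_counts[T] += 1.0;
      }
      cur_dur = 0.0;
      cur_size = 0.0;
      buf.clear();
    }
  }
  return List::create(_["duration"] = wrap(durations),
                      _["size"] = wrap(sizes),
                      _["shape_sums"] = shape_sums,
                      _["shape_counts"] = wrap(shape_counts));
}

// Discrete Ornstein-Uhlenbeck iteration:
//   x_{t+1} = x_t - eta * x_t + (1 - eta) * xi_t,  xi_t ~ N(0, noise_scale)
// [[Rcpp::export]]
NumericVector cpp_ou_walk(double n_steps, double eta, double noise_scale) {
  R_xlen_t n = (R_xlen_t)n_steps;
  NumericVector x(n);
  double pos = 0.0;
  for (R_xlen_t t = 0; t < n; ++t) {
    pos += -eta * pos + (1.0 - eta) * norm_rand() * noise_scale;
    x[t] = pos;
  }
  return x;
}

// +/-1 walk whose increments persist with probability `persist`
// (0.5 = memoryless; >0.5 positively correlated; <0.5 anticorrelated).
// [[Rcpp::export]]
NumericVector cpp_persistent_walk(double n_steps, double persist) {
  R_xlen_t n = (R_xlen_t)n_steps;
  NumericVector x(n);
  double pos = 0.0;
  int step = (unif_rand() < 0.5) ? 1 : -1;
  for (R_xlen_t t = 0; t < n; ++t) {
    if (t > 0 && unif_rand() >= persist) step = -step;
    pos += step;
    x[t] = pos;
  }
  return x;
}
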