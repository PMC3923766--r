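#include <Rcpp.h>
using namespace Rcpp;

// Elementary-step engine for the homeostatic damage-segregation model.
//
// One elementary step (one selection):
//   1. draw cell i uniformly from N
//   2. with probability damages[i] the cell goes apoptotic, else nothing changes
//   3. on death, draw the divider: uniform over the other N-1 cells (well mixed)
//      or uniform over the two ring neighbours of i (ring)
//   4. draw mutated ~ Bernoulli(p)
//   5. daughters: unmutated -> (d, d); mutated symmetric -> both d + delta/2;
//      mutated asymmetric -> (d + delta, d); clamp at 1 per daughter
//   6. place the (high, low) pair on slots (i, divider) with equal probability
//
// The mutation and placement draws are consumed on every division (even when the
// outcome is unobservable) so the RNG stream layout is fixed.
//
// Uses R's RNG (unif_rand) so set.seed() in R governs reproducibility exactly.
//
// mode: 0 = symmetric, 1 = asymmetric
// topology: 0 = well_mixed, 1 = ring_1d
// stop_criterion: 0 = none, 1 = f0_zero (or all damage 1), 2 = all_damage_one

static inline int draw_unif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1; // guards unif_rand() == 1.0 (cannot occur, but cheap)
  return k;
}

struct StepOutcome {
  bool died;
  int i, j;
};

static inline StepOutcome do_step(double* d, int* inc, int N,
                                  double eps, double p, double delta,
                                  int mode, int topology,
                                  int& n_eps, int& n_one) {
  StepOutcome out;
  out.i = draw_unif_int(N);
  double u = unif_rand();
  out.died = (u < d[out.i]);
  out.j = -1;
  if (!out.died) return out;

  int i = out.i, j;
  if (topology == 0) {
    j = draw_unif_int(N - 1);
    if (j >= i) j++;
  } else {
    j = (unif_rand() < 0.5) ? (i - 1 + N) % N : (i + 1) % N;
  }
  out.j = j;

  double dp = d[j];
  int ip = inc[j];
  bool mutated = (unif_rand() < p);
  double d_hi, d_lo;
  int inc_hi, inc_lo;
  if (!mutated) {
    d_hi = d_lo = dp;
    inc_hi = inc_lo = ip;
  } else if (mode == 0) {
    double v = dp + delta / 2.0;
    if (v > 1.0) v = 1.0;
    d_hi = d_lo = v;
    inc_hi = inc_lo = ip + 1;
  } else {
    d_hi = dp + delta;
    if (d_hi > 1.0) d_hi = 1.0;
    d_lo = dp;
    inc_hi = ip + 1;
    inc_lo = ip;
  }
  bool hi_to_vacancy = (unif_rand() < 0.5);

  // update slots i (vacancy) and j (divider), maintaining exact-equality counters
  double old_i = d[i], old_j = d[j];
  double new_i = hi_to_vacancy ? d_hi : d_lo;
  double new_j = hi_to_vacancy ? d_lo : d_hi;
  n_eps += (new_i == eps) - (old_i == eps) + (new_j == eps) - (old_j == eps);
  n_one += (new_i == 1.0) - (old_i == 1.0) + (new_j == 1.0) - (old_j == 1.0);
  d[i] = new_i;
  d[j] = new_j;
  inc[i] = hi_to_vacancy ? inc_hi : inc_lo;
  inc[j] = hi_to_vacancy ? inc_lo : inc_hi;
  return out;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector damages0, IntegerVector increments0,
                double t_steps0,
                double epsilon, double p, double delta,
                int mode, int topology,
                double n_steps_max, int record_every,
                int stop_criterion, bool record_kymograph,
                int n_hist_bins) {
  int N = damages0.size();
  std::vector<double> d(damages0.begin(), damages0.end());
  std::vector<int> inc(increments0.begin(), increments0.end());

  int n_eps = 0, n_one = 0;
  for (int c = 0; c < N; c++) {
    if (d[c] == epsilon) n_eps++;
    if (d[c] == 1.0) n_one++;
  }

  long long steps_max = (long long)n_steps_max;
  int n_rec_max = (record_every > 0) ? (int)(steps_max / record_every) + 1 : 1;
  NumericMatrix summary(n_rec_max, 3);      // t, mean_damage, f0
  NumericMatrix hist(n_rec_max, n_hist_bins + 1);
  NumericMatrix kymo = record_kymograph ? NumericMatrix(n_rec_max, N)
                                        : NumericMatrix(0, 0);
  int n_rec = 0;

  bool collapsed = false;
  long long collapse_step = -1;

  GetRNGstate();

  long long step = 0;
  // record helper as a lambda
  auto record = [&](long long at_step) {
    double sum = 0.0;
    for (int c = 0; c < N; c++) sum += d[c];
    summary(n_rec, 0) = (t_steps0 + (double)at_step) / N;
    summary(n_rec, 1) = sum / N;
    summary(n_rec, 2) = (double)n_eps / N;
    for (int c = 0; c < N; c++) {
      int b = inc[c];
      if (b > n_hist_bins) b = n_hist_bins;
      hist(n_rec, b) += 1.0 / N;
    }
    if (record_kymograph)
      for (int c = 0; c < N; c++) kymo(n_rec, c) = d[c];
    n_rec++;
  };

  auto hit = [&]() -> bool {
    if (stop_criterion == 1) return (n_eps == 0 || n_one == N);
    if (stop_criterion == 2) return (n_one == N);
    return false;
  };

  if (record_every > 0) record(0);
  if (hit()) {
    collapsed = true;
    collapse_step = 0;
  } else {
    for (step = 1; step <= steps_max; step++) {
      do_step(d.data(), inc.data(), N, epsilon, p, delta, mode, topology,
              n_eps, n_one);
      if (record_every > 0 && step % record_every == 0) record(step);
      if (stop_criterion != 0 && hit()) {
        collapsed = true;
        collapse_step = step;
        break;
      }
      if (step % 1048576 == 0) Rcpp::checkUserInterrupt();
    }
    if (step > steps_max) step = steps_max;
  }

  PutRNGstate();

  return List::create(
      _["summary"] = summary(Range(0, std::max(n_rec - 1, 0)), Range(0, 2)),
      _["hist"] = hist(Range(0, std::max(n_rec - 1, 0)), Range(0, n_hist_bins)),
      _["kymograph"] = kymo,
      _["n_rec"] = n_rec,
      _["damages"] = NumericVector(d.begin(), d.end()),
      _["increments"] = IntegerVector(inc.begin(), inc.end()),
      _["t_steps"] = t_steps0 + (double)(collapsed ? collapse_step : step),
      _["collapsed"] = collapsed,
      _["collapse_t_steps"] = (double)collapse_step);
}

// Draw n_samples independent one-step outcomes from a fixed state; returns the
// resulting damage vectors row-wise (for empirical transition-frequency checks).
// [[Rcpp::export(name = ".engine_one_step_samples")]]
NumericMatrix engine_one_step_samples(NumericVector damages0,
                                      IntegerVector increments0,
                                      double epsilon, double p, double delta,
                                      int mode, int topology, int n_samples) {
  int N = damages0.size();
  NumericMatrix out(n_samples, N);
  std::vector<double> d(N);
  std::vector<int> inc(N);
  int n_eps, n_one;
  GetRNGstate();
  for (int s = 0; s < n_samples; s++) {
    std::copy(damages0.begin(), damages0.end(), d.begin());
    std::copy(increments0.begin(), increments0.end(), inc.begin());
    n_eps = n_one = 0;
    do_step(d.data(), inc.data(), N, epsilon, p, delta, mode, topology,
            n_eps, n_one);
    for (int c = 0; c < N; c++) out(s, c) = d[c];
  }
  PutRNGstate();
  return out;
}
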