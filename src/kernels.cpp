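#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time Markov chain (Gillespie) kernels shared by the trajectory
// sampler, the PDA Monte-Carlo occupancy integrator, and the photon-stream
// simulator. All randomness goes through R's RNG so set.seed() controls it.

static int draw_categorical(const double *p, int n) {
  double u = unif_rand();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += p[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

// [[Rcpp::export]]
List cpp_ctmc_trajectory(NumericMatrix Q, NumericVector p0, double duration,
                         int init_state) {
  int S = Q.nrow();
  std::vector<double> jumps;
  std::vector<int> states;
  int s = (init_state >= 1) ? (init_state - 1)
                            : draw_categorical(p0.begin(), S);
  double t = 0.0;
  jumps.push_back(0.0);
  states.push_back(s + 1);
  for (;;) {
    double lambda = -Q(s, s);
    if (lambda <= 0.0) break;
    t += exp_rand() / lambda;
    if (t >= duration) break;
    // next state proportional to off-diagonal rates
    double u = unif_rand() * lambda, acc = 0.0;
    int nxt = s;
    for (int j = 0; j < S; ++j) {
      if (j == s) continue;
      acc += Q(s, j);
      if (u <= acc) { nxt = j; break; }
      nxt = j;  // fallback to last candidate on rounding
    }
    s = nxt;
    jumps.push_back(t);
    states.push_back(s + 1);
  }
  return List::create(_["jump_times"] = wrap(jumps),
                      _["states"] = wrap(states),
                      _["duration"] = duration);
}

// Fraction of the window [0, duration] spent in each state, for n independent
// equilibrium-start replicates. Rows are replicates, columns states.
// [[Rcpp::export]]
NumericMatrix cpp_occupancy_fractions(NumericMatrix Q, NumericVector p0,
                                      double duration, int n) {
  int S = Q.nrow();
  NumericMatrix out(n, S);
  for (int r = 0; r < n; ++r) {
    int s = draw_categorical(p0.begin(), S);
    double t = 0.0;
    while (t < duration) {
      double lambda = -Q(s, s);
      double dwell;
      if (lambda <= 0.0) {
        dwell = duration - t;
      } else {
        dwell = exp_rand() / lambda;
        if (t + dwell > duration) dwell = duration - t;
      }
      out(r, s) += dwell;
      t += dwell;
      if (lambda <= 0.0) break;
      if (t >= duration) break;
      double u = unif_rand() * lambda, acc = 0.0;
      int nxt = s;
      for (int j = 0; j < S; ++j) {
        if (j == s) continue;
        acc += Q(s, j);
        if (u <= acc) { nxt = j; break; }
        nxt = j;
      }
      s = nxt;
    }
    for (int j = 0; j < S; ++j) out(r, j) /= duration;
  }
  return out;
}
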