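#include <Rcpp.h>
using namespace Rcpp;

// Embedded jump chain of the TGP sub-process (u = 0 between injections).
// From a transient state k in (0, N) the three event rates are
//   to E   : k * v                      (type-I birth that mutates)
//   k -> k+1: k * (1 - v) * (N - k) / N (non-mutant type-I offspring
//                                        replaces a wild-type cell)
//   k -> k-1: (N - k) * k / N           (wild-type offspring replaces a
//                                        type-I cell)
// Self-replacements are self-loops of the continuous-time chain and are
// absent from the embedded chain; they do not affect absorption.
//
// Return codes: 0 = absorbed at 0, 1 = absorbed at N, 2 = absorbed at E.
// With u > 0 and k = 0 the chain is re-seeded 0 -> 1 (one counted step),
// so the full process can only end at N or E.

// [[Rcpp::export]]
List tgp_run_trajectory_cpp(int N, double v, double u, int k0,
                            double step_cap) {
  if (N < 2) stop("N must be >= 2");
  if (k0 < 0 || k0 > N) stop("k0 must lie in [0, N]");
  double steps = 0.0;
  int k = k0;
  int code = -1;
  for (;;) {
    if (k == N) { code = 1; break; }
    if (k == 0) {
      if (u > 0.0) { k = 1; steps += 1.0; continue; }
      code = 0; break;
    }
    double rE = (double)k * v;
    double rUp = (double)k * (1.0 - v) * (double)(N - k) / (double)N;
    double rDown = (double)k * (double)(N - k) / (double)N;
    double tot = rE + rUp + rDown;
    double x = unif_rand() * tot;
    steps += 1.0;
    if (x < rUp) {
      ++k;
    } else if (x < rUp + rDown) {
      --k;
    } else {
      code = 2; break;
    }
    if (steps >= step_cap)
      stop("trajectory exceeded the step cap (%.0f embedded jumps) at state "
           "k = %d; raise `step_cap` if this is expected", step_cap, k);
  }
  return List::create(_["code"] = code, _["steps"] = steps);
}

// Batch runner: `reps` independent trajectories drawn from one continuous
// RNG stream (the R wrapper seeds the stream).  Returns the per-replicate
// absorption codes and step counts.

// [[Rcpp::export]]
List tgp_run_batch_cpp(int N, double v, double u, int k0, int reps,
                       double step_cap) {
  IntegerVector code(reps);
  NumericVector steps(reps);
  for (int i = 0; i < reps; ++i) {
    List out = tgp_run_trajectory_cpp(N, v, u, k0, step_cap);
    code[i] = as<int>(out["code"]);
    steps[i] = as<double>(out["steps"]);
  }
  return List::create(_["code"] = code, _["steps"] = steps);
}
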