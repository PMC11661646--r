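// One-dimensional birth-death process used as an exactly tractable benchmark
// for the forward-flux sampler: birth at constant rate b, death at rate d*n.
// Observation protocol matches the sampler's: the count is inspected at the
// end of every propagation chunk, so "reaching K by time T" means n >= K at
// one of the chunk boundaries.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static int bd_propagate(int n, double b, double d, double t_dur) {
  double t = 0.0;
  for (;;) {
    double a = b + d * n;
    if (a <= 0.0) break;
    double dt = -std::log(unif_rand()) / a;
    if (t + dt > t_dur) break;
    t += dt;
    if (unif_rand() * a < b) ++n; else --n;
  }
  return n;
}

// [[Rcpp::export(name = ".bd_run_cpp")]]
int bd_run_cpp(int n0, double b, double d, double t_dur) {
  RNGScope scope;
  return bd_propagate(n0, b, d, t_dur);
}

// Direct-simulation estimate of first-passage over K observed at chunk ends.
// Returns number of hits out of nrep replicates.
// [[Rcpp::export(name = ".bd_fp_direct_cpp")]]
int bd_fp_direct_cpp(int n0, double b, double d, double t_chunk, int n_chunks,
                     int K, int nrep) {
  RNGScope scope;
  int hits = 0;
  for (int r = 0; r < nrep; ++r) {
    int n = n0;
    for (int j = 0; j < n_chunks; ++j) {
      n = bd_propagate(n, b, d, t_chunk);
      if (n >= K) { ++hits; break; }
    }
  }
  return hits;
}
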