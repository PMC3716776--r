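#include <Rcpp.h>
using namespace Rcpp;

// Simulate a DNA sequence from an order-k Markov chain ("De Bruijn chain").
//
// trans: (4^k) x 4 row-stochastic matrix; row order is the lexicographic
// enumeration of k-mers over A,C,G,T (A=0,...,T=3), matching
// Biostrings::oligonucleotideFrequency(). init: length-4 start-base
// probabilities used to draw the first k bases independently.
// Uses R's RNG so set.seed() controls the output.
// [[Rcpp::export(name = ".simulate_chain_cpp")]]
std::string simulate_chain(int n, NumericMatrix trans, NumericVector init,
                           int k) {
  if (n < k) stop("sequence length must be at least the chain order");
  static const char bases[] = {'A', 'C', 'G', 'T'};
  std::string out(n, 'A');

  // cumulative rows for inverse-CDF sampling
  int nstate = trans.nrow();
  std::vector<double> cum(nstate * 4);
  for (int s = 0; s < nstate; ++s) {
    double acc = 0.0;
    for (int b = 0; b < 4; ++b) {
      acc += trans(s, b);
      cum[s * 4 + b] = acc;
    }
    if (acc <= 0) stop("transition row %d sums to zero", s + 1);
    for (int b = 0; b < 4; ++b) cum[s * 4 + b] /= acc;
  }
  double ci[4];
  double acc = 0.0;
  for (int b = 0; b < 4; ++b) { acc += init[b]; ci[b] = acc; }
  for (int b = 0; b < 4; ++b) ci[b] /= acc;

  GetRNGstate();
  int state = 0;
  const int mask = nstate - 1;  // nstate = 4^k, power of two times...
  // nstate is 4^k so (state*4 + b) % nstate drops the oldest base
  for (int i = 0; i < k && i < n; ++i) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > ci[b]) ++b;
    out[i] = bases[b];
    state = ((state << 2) | b) & mask;
  }
  for (int i = k; i < n; ++i) {
    double u = unif_rand();
    const double* row = &cum[state * 4];
    int b = 0;
    while (b < 3 && u > row[b]) ++b;
    out[i] = bases[b];
    state = ((state << 2) | b) & mask;
  }
  PutRNGstate();
  return out;
}
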