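#include <Rcpp.h>
using namespace Rcpp;

// Sample `count` sequences of length `len` from an order-d Markov chain.
// mu: stationary distribution over 4^d contexts (for d = 0 over letters),
// trans: 4^d x 4 row-stochastic transition matrix.
// Uses R's RNG so results respect set.seed().
// Letters are returned 1-based (A=1, C=2, G=3, T=4), concatenated.
// [[Rcpp::export]]
IntegerVector cpp_sample_markov(int count, int len, int d, NumericVector mu,
                                NumericMatrix trans) {
  IntegerVector out(static_cast<R_xlen_t>(count) * len);
  const int nctx = trans.nrow();
  // cumulative per-row transition probabilities
  std::vector<double> cum(static_cast<size_t>(nctx) * 4);
  for (int r = 0; r < nctx; ++r) {
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
      acc += trans(r, c);
      cum[static_cast<size_t>(r) * 4 + c] = acc;
    }
  }
  std::vector<double> mucum(mu.size());
  {
    double acc = 0.0;
    for (int i = 0; i < mu.size(); ++i) { acc += mu[i]; mucum[i] = acc; }
  }
  const int ctxmod = d > 1 ? nctx / 4 : 1;
  R_xlen_t pos = 0;
  for (int s = 0; s < count; ++s) {
    int ctx = 0;  // 0-based context code
    int i = 0;
    if (d > 0) {
      // first d letters drawn jointly from mu
      double u = unif_rand();
      int w = 0;
      while (w < static_cast<int>(mucum.size()) - 1 && u > mucum[w]) ++w;
      // decode big-endian word w into letters
      for (int j = d - 1; j >= 0; --j)
        out[pos + j] = (w / static_cast<int>(std::pow(4.0, d - 1 - j))) % 4 + 1;
      pos += d;
      i = d;
      ctx = w;
    }
    for (; i < len; ++i) {
      double u = unif_rand();
      const double *row = &cum[static_cast<size_t>(ctx) * 4];
      int x = 0;
      while (x < 3 && u > row[x]) ++x;
      out[pos++] = x + 1;
      if (d == 1) ctx = x;
      else if (d > 1) ctx = (ctx % ctxmod) * 4 + x;
    }
  }
  return out;
}
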