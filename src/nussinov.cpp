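#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Pair weight in kcal/mol: GC -3, AU -2, GU -1, otherwise no pair (0 /
// disallowed). Simplified base-pair-counting energy model.
static inline double pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // sentinel: not pairable
}

// Minimum "energy" over all non-crossing secondary structures with a
// minimum hairpin loop of `minloop` unpaired nt between paired bases.
static double mfe_one(const std::string& s, int minloop) {
  int n = s.size();
  if (n < minloop + 2) return 0.0;
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i][j - 1]; // j unpaired
      for (int k = i; k <= j - minloop - 1; ++k) {
        double w = pair_w(s[k], s[j]);
        if (w > 0) continue;
        double left = (k > i) ? E[i][k - 1] : 0.0;
        double inside = (k + 1 <= j - 1) ? E[k + 1][j - 1] : 0.0;
        double v = left + w + inside;
        if (v < best) best = v;
      }
      E[i][j] = best;
    }
  }
  return E[0][n - 1];
}

// [[Rcpp::export(name = ".nussinov_mfe")]]
NumericVector nussinov_mfe_cpp(CharacterVector seqs, int minloop = 3) {
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = mfe_one(s, minloop);
  }
  return out;
}
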