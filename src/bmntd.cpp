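#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted between-community mean nearest taxon distance for all
// sample pairs. comm: samples x taxa relative abundances (rows sum to 1 over
// present taxa); dist: taxa x taxa patristic distances, column order matching
// comm columns. When weighted is false every present taxon gets equal weight.
// The null model recomputes this for hundreds of tip permutations, so the
// inner loop lives here.
// [[Rcpp::export]]
NumericMatrix bmntd_pairs_cpp(NumericMatrix comm, NumericMatrix dist,
                              bool weighted) {
  const int S = comm.nrow();
  const int T = comm.ncol();

  // Present-taxon index lists and weights per sample
  std::vector<std::vector<int>> idx(S);
  std::vector<std::vector<double>> w(S);
  for (int s = 0; s < S; ++s) {
    double tot = 0.0;
    for (int t = 0; t < T; ++t)
      if (comm(s, t) > 0) { idx[s].push_back(t); tot += comm(s, t); }
    const int n = idx[s].size();
    w[s].resize(n);
    for (int k = 0; k < n; ++k)
      w[s][k] = weighted ? comm(s, idx[s][k]) / tot : 1.0 / n;
  }

  NumericMatrix out(S, S);
  for (int a = 0; a < S; ++a) {
    for (int b = a + 1; b < S; ++b) {
      const std::vector<int>&ia = idx[a], &ib = idx[b];
      if (ia.empty() || ib.empty()) {
        out(a, b) = out(b, a) = NA_REAL;
        continue;
      }
      double sa = 0.0, sb = 0.0;
      for (size_t k = 0; k < ia.size(); ++k) {
        double mn = R_PosInf;
        for (size_t l = 0; l < ib.size(); ++l) {
          const double d = dist(ia[k], ib[l]);
          if (d < mn) mn = d;
        }
        sa += w[a][k] * mn;
      }
      for (size_t l = 0; l < ib.size(); ++l) {
        double mn = R_PosInf;
        for (size_t k = 0; k < ia.size(); ++k) {
          const double d = dist(ia[k], ib[l]);
          if (d < mn) mn = d;
        }
        sb += w[b][l] * mn;
      }
      out(a, b) = out(b, a) = 0.5 * (sa + sb);
    }
  }
  return out;
}
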