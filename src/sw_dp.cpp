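#include <Rcpp.h>
using namespace Rcpp;

// Full-matrix Smith-Waterman local alignment score with affine gaps.
// A gap of length k costs open + k * ext (the first gapped position pays
// open + ext).  Quadratic time and memory in sequence length; intended as
// an independent validation reference, not a production aligner.
// [[Rcpp::export]]
double sw_score_dp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                   double open, double ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fcol(m + 1, NEG); // gap in a (vertical)
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double E = NEG; // gap in b (horizontal), row-local
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(E - ext, Hcur[j - 1] - open - ext);
      Fcol[j] = std::max(Fcol[j] - ext, Hprev[j] - open - ext);
      double diag = Hprev[j - 1] + mat(a[i - 1], b[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(E, Fcol[j])));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}
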