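#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch style) alignment maximizing total score with a
// linear gap penalty. Ties are broken deterministically: diagonal, then up
// (gap in the column sequence), then left.
//
// Returns a k x 2 matrix of 1-based (row, col) index pairs, strictly
// increasing in both coordinates.
// [[Rcpp::export]]
IntegerMatrix dp_align_cpp(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<double> H((n + 1) * (m + 1));
  std::vector<unsigned char> P((n + 1) * (m + 1)); // 0 diag, 1 up, 2 left
  const int W = m + 1;
  H[0] = 0.0;
  for (int j = 1; j <= m; ++j) { H[j] = j * gap; P[j] = 2; }
  for (int i = 1; i <= n; ++i) { H[i * W] = i * gap; P[i * W] = 1; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double diag = H[(i - 1) * W + (j - 1)] + S(i - 1, j - 1);
      const double up = H[(i - 1) * W + j] + gap;
      const double left = H[i * W + (j - 1)] + gap;
      double best = diag;
      unsigned char ptr = 0;
      if (up > best) { best = up; ptr = 1; }
      if (left > best) { best = left; ptr = 2; }
      H[i * W + j] = best;
      P[i * W + j] = ptr;
    }
  }
  std::vector<int> ri, rj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char ptr = (i > 0 && j > 0) ? P[i * W + j] : (i > 0 ? 1 : 2);
    if (ptr == 0) { ri.push_back(i); rj.push_back(j); --i; --j; }
    else if (ptr == 1) { --i; }
    else { --j; }
  }
  const int k = (int) ri.size();
  IntegerMatrix out(k, 2);
  for (int t = 0; t < k; ++t) {
    out(t, 0) = ri[k - 1 - t];
    out(t, 1) = rj[k - 1 - t];
  }
  return out;
}
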