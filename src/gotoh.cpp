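// Global profile-profile alignment (Gotoh affine-gap DP) on a precomputed
// column-pair score matrix. Used by the progressive codon-aware aligner:
// R computes S[i,j] = average substitution score between column i of profile
// A and column j of profile B; this routine returns the maximal-score global
// path. Opening a gap costs gap_open + gap_ext, extending costs gap_ext.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gotoh_profile(NumericMatrix S, double gap_open, double gap_ext) {
  const int la = S.nrow(), lb = S.ncol();
  const double NEG = -1e30;
  const double open = gap_open + gap_ext;

  // DP matrices: 0 = M (match), 1 = X (gap in B, consume A), 2 = Y (gap in A)
  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X((la + 1) * (lb + 1), NEG);
  std::vector<double> Y((la + 1) * (lb + 1), NEG);
  std::vector<unsigned char> tbM((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tbX((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tbY((la + 1) * (lb + 1), 0);
  auto idx = [lb](int i, int j) { return i * (lb + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[idx(i, 0)] = -open - gap_ext * (i - 1);
    tbX[idx(i, 0)] = 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[idx(0, j)] = -open - gap_ext * (j - 1);
    tbY[idx(0, j)] = 2;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      // M: diagonal
      double m0 = M[idx(i - 1, j - 1)], m1 = X[idx(i - 1, j - 1)],
             m2 = Y[idx(i - 1, j - 1)];
      int bm = 0; double bv = m0;
      if (m1 > bv) { bv = m1; bm = 1; }
      if (m2 > bv) { bv = m2; bm = 2; }
      M[idx(i, j)] = bv + S(i - 1, j - 1);
      tbM[idx(i, j)] = (unsigned char)bm;
      // X: consume A row i
      double x0 = M[idx(i - 1, j)] - open, x1 = X[idx(i - 1, j)] - gap_ext,
             x2 = Y[idx(i - 1, j)] - open;
      bm = 0; bv = x0;
      if (x1 > bv) { bv = x1; bm = 1; }
      if (x2 > bv) { bv = x2; bm = 2; }
      X[idx(i, j)] = bv;
      tbX[idx(i, j)] = (unsigned char)bm;
      // Y: consume B column j
      double y0 = M[idx(i, j - 1)] - open, y1 = X[idx(i, j - 1)] - open,
             y2 = Y[idx(i, j - 1)] - gap_ext;
      bm = 0; bv = y0;
      if (y1 > bv) { bv = y1; bm = 1; }
      if (y2 > bv) { bv = y2; bm = 2; }
      Y[idx(i, j)] = bv;
      tbY[idx(i, j)] = (unsigned char)bm;
    }
  }

  int state = 0;
  double score = M[idx(la, lb)];
  if (X[idx(la, lb)] > score) { score = X[idx(la, lb)]; state = 1; }
  if (Y[idx(la, lb)] > score) { score = Y[idx(la, lb)]; state = 2; }

  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM[idx(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX[idx(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = tbY[idx(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = score);
}
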