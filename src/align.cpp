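// Global affine-gap alignment (Gotoh) over an arbitrary position-specific
// column score matrix. A gap of length k costs gapOpen + k * gapExtend.
// Traceback ties break deterministically: diagonal, then up (gap in b),
// then left (gap in a).

#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".needleAffine")]]
List needleAffine(NumericMatrix S, double gapOpen, double gapExtend) {
  const int n = S.nrow();   // length of a
  const int m = S.ncol();   // length of b
  if (n < 1 || m < 1) stop("empty sequence");

  // state 0 = M (diagonal), 1 = X (a_i vs gap, "up"), 2 = Y (gap vs b_j)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -gapOpen - i * gapExtend;
    pX[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -gapOpen - j * gapExtend;
    pY[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: align a_i with b_j; predecessor preference M > X > Y on ties
      {
        double vM = M[at(i - 1, j - 1)], vX = X[at(i - 1, j - 1)],
               vY = Y[at(i - 1, j - 1)];
        double best = vM; signed char p = 0;
        if (vX > best) { best = vX; p = 1; }
        if (vY > best) { best = vY; p = 2; }
        if (best > NEG_INF) {
          M[at(i, j)] = best + S(i - 1, j - 1);
          pM[at(i, j)] = p;
        }
      }
      // X: a_i against a gap
      {
        double vM = M[at(i - 1, j)] - gapOpen - gapExtend;
        double vX = X[at(i - 1, j)] - gapExtend;
        double vY = Y[at(i - 1, j)] - gapOpen - gapExtend;
        double best = vM; signed char p = 0;
        if (vX > best) { best = vX; p = 1; }
        if (vY > best) { best = vY; p = 2; }
        X[at(i, j)] = best; pX[at(i, j)] = p;
      }
      // Y: gap against b_j
      {
        double vM = M[at(i, j - 1)] - gapOpen - gapExtend;
        double vX = X[at(i, j - 1)] - gapOpen - gapExtend;
        double vY = Y[at(i, j - 1)] - gapExtend;
        double best = vM; signed char p = 0;
        if (vX > best) { best = vX; p = 1; }
        if (vY > best) { best = vY; p = 2; }
        Y[at(i, j)] = best; pY[at(i, j)] = p;
      }
    }
  }

  double score = M[at(n, m)]; int state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::vector<int> ai, bi;  // reverse order; 0 marks a gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = pM[at(i, j)];
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      state = pX[at(i, j)];
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      state = pY[at(i, j)];
      --j;
    }
  }

  const int len = ai.size();
  IntegerVector aIdx(len), bIdx(len);
  for (int c = 0; c < len; ++c) {
    aIdx[c] = ai[len - 1 - c] == 0 ? NA_INTEGER : ai[len - 1 - c];
    bIdx[c] = bi[len - 1 - c] == 0 ? NA_INTEGER : bi[len - 1 - c];
  }
  return List::create(_["score"] = score, _["aIdx"] = aIdx, _["bIdx"] = bIdx);
}
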