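#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP).
// A gap of length k costs gap_open + k * gap_extend.
// States: 0 = match/mismatch (diagonal), 1 = gap in b (consumes a; "up"),
// 2 = gap in a (consumes b; "left"). Ties prefer diagonal, then up.
//
// a, b: 0-based indices into the scoring matrix. Returns the optimal score
// and the edit path as operations from the start of the alignment
// (0 = diagonal, 1 = up, 2 = left).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix score,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double open1 = gap_open + gap_extend;  // first gapped residue

  // rolling score rows; full byte traceback
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  // ptr[state][(i*(m+1))+j] = predecessor state
  std::vector<unsigned char> ptrM((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> ptrX((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> ptrY((size_t)(n + 1) * (m + 1));

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG; Xprev[j] = NEG;
    Yprev[j] = -(gap_open + gap_extend * j);
    ptrY[j] = 2;  // continue left gap
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG; Ycur[0] = NEG;
    Xcur[0] = -(gap_open + gap_extend * i);
    ptrX[(size_t)i * (m + 1)] = 1;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * (m + 1) + j;
      // M: from any state diagonally
      {
        double best = Mprev[j - 1]; unsigned char st = 0;
        if (Xprev[j - 1] > best) { best = Xprev[j - 1]; st = 1; }
        if (Yprev[j - 1] > best) { best = Yprev[j - 1]; st = 2; }
        Mcur[j] = best + score(ai, b[j - 1]);
        ptrM[idx] = st;
      }
      // X: gap in b, consume a (move down)
      {
        double best = Mprev[j] - open1; unsigned char st = 0;
        if (Xprev[j] - gap_extend > best) { best = Xprev[j] - gap_extend; st = 1; }
        if (Yprev[j] - open1 > best) { best = Yprev[j] - open1; st = 2; }
        Xcur[j] = best;
        ptrX[idx] = st;
      }
      // Y: gap in a, consume b (move right)
      {
        double best = Mcur[j - 1] - open1; unsigned char st = 0;
        if (Xcur[j - 1] - open1 > best) { best = Xcur[j - 1] - open1; st = 1; }
        if (Ycur[j - 1] - gap_extend > best) { best = Ycur[j - 1] - gap_extend; st = 2; }
        Ycur[j] = best;
        ptrY[idx] = st;
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  double best = Mprev[m]; unsigned char state = 0;
  if (Xprev[m] > best) { best = Xprev[m]; state = 1; }
  if (Yprev[m] > best) { best = Yprev[m]; state = 2; }

  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) { ops.push_back(0); state = ptrM[idx]; --i; --j; }
    else if (state == 1) { ops.push_back(1); state = ptrX[idx]; --i; }
    else { ops.push_back(2); state = ptrY[idx]; --j; }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = best,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
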