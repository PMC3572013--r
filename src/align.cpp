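#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment of two column profiles (Gotoh, three matrices).
// S12[i, j] is the substitution score for matching column i of profile 1
// with column j of profile 2. Gap convention: a run of k gap columns costs
// gap_open + (k - 1) * gap_extend, so linear costs are obtained by setting
// gap_open == gap_extend.
//
// Tie-breaking is fixed so outputs are byte-stable: on equal score prefer
// match (1) over delete (2, gap in profile 2 / consume profile 1) over
// insert (3, gap in profile 1 / consume profile 2), both when filling the
// matrices and in the traceback.
//
// Returns list(ops = integer vector of 1/2/3 in alignment order, score).
// [[Rcpp::export]]
List C_profile_align(NumericMatrix S12, double gap_open, double gap_extend) {
  const int n = S12.nrow(), m = S12.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state matrices, (n+1) x (m+1)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG); // gap in profile 2, consumes i
  std::vector<double> Y((n + 1) * (m + 1), NEG); // gap in profile 1, consumes j
  // traceback: predecessor state for each cell/state (0 = M, 1 = X, 2 = Y)
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; i++) {
    X[IDX(i, 0)] = gap_open + (i - 1) * gap_extend;
    tbX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; j++) {
    Y[IDX(0, j)] = gap_open + (j - 1) * gap_extend;
    tbY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      // M: diagonal move, predecessor any state; prefer M > X > Y on ties
      {
        double a = M[IDX(i - 1, j - 1)], b = X[IDX(i - 1, j - 1)],
               c = Y[IDX(i - 1, j - 1)];
        double best = a; signed char st = 0;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        if (best > NEG) {
          M[IDX(i, j)] = best + S12(i - 1, j - 1);
          tbM[IDX(i, j)] = st;
        }
      }
      // X: consume i (gap in profile 2)
      {
        double a = M[IDX(i - 1, j)] + gap_open;
        double b = X[IDX(i - 1, j)] + gap_extend;
        double c = Y[IDX(i - 1, j)] + gap_open;
        double best = a; signed char st = 0;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        if (best > NEG) { X[IDX(i, j)] = best; tbX[IDX(i, j)] = st; }
      }
      // Y: consume j (gap in profile 1)
      {
        double a = M[IDX(i, j - 1)] + gap_open;
        double b = X[IDX(i, j - 1)] + gap_open;
        double c = Y[IDX(i, j - 1)] + gap_extend;
        double best = a; signed char st = 0;
        if (b > best) { best = b; st = 1; }
        if (c > best) { best = c; st = 2; }
        if (best > NEG) { Y[IDX(i, j)] = best; tbY[IDX(i, j)] = st; }
      }
    }
  }

  // terminal state: prefer M > X > Y on ties
  double sM = M[IDX(n, m)], sX = X[IDX(n, m)], sY = Y[IDX(n, m)];
  double score = sM; int st = 0;
  if (sX > score) { score = sX; st = 1; }
  if (sY > score) { score = sY; st = 2; }

  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      ops.push_back(1);
      st = tbM[IDX(i, j)];
      i--; j--;
    } else if (st == 1) {
      ops.push_back(2);
      st = tbX[IDX(i, j)];
      i--;
    } else {
      ops.push_back(3);
      st = tbY[IDX(i, j)];
      j--;
    }
  }
  std::reverse(ops.begin(), ops.end());
#undef IDX
  return List::create(_["ops"] = wrap(ops), _["score"] = score);
}
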