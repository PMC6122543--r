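#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gotoh affine-gap dynamic programming on a precomputed column-score matrix S
// (rows = positions of sequence/profile A, cols = B). Linear gaps are the
// special case gap_open == gap_extend. Tie-break during traceback prefers
// diagonal > up (gap in B) > left (gap in A), applied when choosing both the
// final state and each predecessor, so output is deterministic.
//
// States: 0 = M (a_i aligned to b_j), 1 = X (a_i against gap, "up"),
//         2 = Y (b_j against gap, "left").

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List dp_global_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // predecessor state for each cell/state; -1 = start
  std::vector<signed char> pM((n + 1) * (m + 1), -1);
  std::vector<signed char> pX((n + 1) * (m + 1), -1);
  std::vector<signed char> pY((n + 1) * (m + 1), -1);
  int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = gap_open + (i - 1) * gap_extend;
    pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = gap_open + (j - 1) * gap_extend;
    pY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: from any state at (i-1, j-1); prefer M > X > Y on ties
      double d0 = M[IDX(i - 1, j - 1)], d1 = X[IDX(i - 1, j - 1)],
             d2 = Y[IDX(i - 1, j - 1)];
      double best = d0; signed char arg = 0;
      if (d1 > best) { best = d1; arg = 1; }
      if (d2 > best) { best = d2; arg = 2; }
      if (best > NEG_INF / 2) {
        M[IDX(i, j)] = best + S(i - 1, j - 1);
        pM[IDX(i, j)] = arg;
      }
      // X (up, consume a_i): open from M/Y, extend from X
      double xo = (M[IDX(i - 1, j)] > NEG_INF / 2) ? M[IDX(i - 1, j)] + gap_open : NEG_INF;
      double xx = (X[IDX(i - 1, j)] > NEG_INF / 2) ? X[IDX(i - 1, j)] + gap_extend : NEG_INF;
      double xy = (Y[IDX(i - 1, j)] > NEG_INF / 2) ? Y[IDX(i - 1, j)] + gap_open : NEG_INF;
      best = xo; arg = 0;
      if (xx > best) { best = xx; arg = 1; }
      if (xy > best) { best = xy; arg = 2; }
      if (best > NEG_INF / 2) { X[IDX(i, j)] = best; pX[IDX(i, j)] = arg; }
      // Y (left, consume b_j)
      double yo = (M[IDX(i, j - 1)] > NEG_INF / 2) ? M[IDX(i, j - 1)] + gap_open : NEG_INF;
      double yx = (X[IDX(i, j - 1)] > NEG_INF / 2) ? X[IDX(i, j - 1)] + gap_open : NEG_INF;
      double yy = (Y[IDX(i, j - 1)] > NEG_INF / 2) ? Y[IDX(i, j - 1)] + gap_extend : NEG_INF;
      best = yo; arg = 0;
      if (yx > best) { best = yx; arg = 1; }
      if (yy > best) { best = yy; arg = 2; }
      if (best > NEG_INF / 2) { Y[IDX(i, j)] = best; pY[IDX(i, j)] = arg; }
    }
  }

  double sM = M[IDX(n, m)], sX = X[IDX(n, m)], sY = Y[IDX(n, m)];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = pM[IDX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = pX[IDX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
    } else {
      prev = pY[IDX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
    }
    if (prev < 0) break;
    state = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}

// Local (Smith-Waterman) variant: best single local alignment. The alignment
// ends and starts on an aligned pair (trailing/leading gaps never improve a
// local score with negative gap penalties).
// [[Rcpp::export]]
List dp_local_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> pM((n + 1) * (m + 1), -1); // -1=fresh start, 0=M,1=X,2=Y
  std::vector<signed char> pX((n + 1) * (m + 1), -1); // 0 = from M, 1 = from X
  std::vector<signed char> pY((n + 1) * (m + 1), -1); // 0 = from M, 2 = from Y
  int W = m + 1;
  double best_score = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d0 = M[IDX(i - 1, j - 1)], d1 = X[IDX(i - 1, j - 1)],
             d2 = Y[IDX(i - 1, j - 1)];
      double best = 0.0; signed char arg = -1;
      if (d0 > best) { best = d0; arg = 0; }
      if (d1 > best) { best = d1; arg = 1; }
      if (d2 > best) { best = d2; arg = 2; }
      double v = best + S(i - 1, j - 1);
      M[IDX(i, j)] = v;
      pM[IDX(i, j)] = arg;
      if (v > best_score) { best_score = v; best_i = i; best_j = j; }

      double xo = M[IDX(i - 1, j)] + gap_open;
      double xx = (X[IDX(i - 1, j)] > NEG_INF / 2) ? X[IDX(i - 1, j)] + gap_extend : NEG_INF;
      if (xo >= xx) { X[IDX(i, j)] = xo; pX[IDX(i, j)] = 0; }
      else          { X[IDX(i, j)] = xx; pX[IDX(i, j)] = 1; }

      double yo = M[IDX(i, j - 1)] + gap_open;
      double yy = (Y[IDX(i, j - 1)] > NEG_INF / 2) ? Y[IDX(i, j - 1)] + gap_extend : NEG_INF;
      if (yo >= yy) { Y[IDX(i, j)] = yo; pY[IDX(i, j)] = 0; }
      else          { Y[IDX(i, j)] = yy; pY[IDX(i, j)] = 2; }
    }
  }

  std::vector<int> ai, bi;
  int i = best_i, j = best_j, state = 0;
  if (best_score > 0) {
    while (true) {
      if (state == 0) {
        signed char prev = pM[IDX(i, j)];
        ai.push_back(i); bi.push_back(j);
        --i; --j;
        if (prev < 0) break;
        state = prev;
      } else if (state == 1) {
        signed char prev = pX[IDX(i, j)];
        ai.push_back(i); bi.push_back(0);
        --i;
        state = (prev == 0) ? 0 : 1;
      } else {
        signed char prev = pY[IDX(i, j)];
        ai.push_back(0); bi.push_back(j);
        --j;
        state = (prev == 0) ? 0 : 2;
      }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best_score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
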