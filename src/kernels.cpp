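#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap dynamic programming kernels shared by the sequence-sequence
// (Needleman-Wunsch) and profile-sequence (Smith-Waterman) aligners.
//
// Convention: a gap of length k costs gapOpen + k * gapExtend, i.e. opening
// a gap charges gapOpen + gapExtend for its first position.
//
// Both kernels take a pre-computed pair-score matrix S (m x n): S(i,j) is the
// score of pairing row item i with column item j. For sequence-sequence
// alignment that is substitution[a_i, b_j]; for profile alignment it is
// pssm[j, residue_i].

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes used in traceback matrices
// predecessor state for each of M (pair), X (gap in columns: row item aligned
// to gap), Y (gap in rows): 0 = from M, 1 = from X, 2 = from Y, 3 = start.

// [[Rcpp::export]]
List cpp_nw_affine(NumericMatrix S, double gapOpen, double gapExtend) {
  int m = S.nrow(), n = S.ncol();
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix tM(m + 1, n + 1), tX(m + 1, n + 1), tY(m + 1, n + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(gapOpen + i * gapExtend);
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gapOpen + j * gapExtend);
    tY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: pair (i, j); predecessor preference M > X > Y
      double bm = M(i - 1, j - 1); int sm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); sm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); sm = 2; }
      M(i, j) = bm + S(i - 1, j - 1); tM(i, j) = sm;

      // X: row item i aligned to a gap
      double bx = M(i - 1, j) - (gapOpen + gapExtend); int sx = 0;
      if (X(i - 1, j) - gapExtend > bx) { bx = X(i - 1, j) - gapExtend; sx = 1; }
      if (Y(i - 1, j) - (gapOpen + gapExtend) > bx) { bx = Y(i - 1, j) - (gapOpen + gapExtend); sx = 2; }
      X(i, j) = bx; tX(i, j) = sx;

      // Y: column item j aligned to a gap
      double by = M(i, j - 1) - (gapOpen + gapExtend); int sy = 0;
      if (X(i, j - 1) - (gapOpen + gapExtend) > by) { by = X(i, j - 1) - (gapOpen + gapExtend); sy = 1; }
      if (Y(i, j - 1) - gapExtend > by) { by = Y(i, j - 1) - gapExtend; sy = 2; }
      Y(i, j) = by; tY(i, j) = sy;
    }
  }

  double best = M(m, n); int state = 0;
  if (X(m, n) > best) { best = X(m, n); state = 1; }
  if (Y(m, n) > best) { best = Y(m, n); state = 2; }

  // traceback: ops coded 0 = pair, 1 = gap in columns (consume row),
  // 2 = gap in rows (consume column); collected reversed
  std::vector<int> ops;
  ops.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      state = tM(i, j); --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      state = tX(i, j); --i;
    } else {
      ops.push_back(2);
      state = tY(i, j); --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// [[Rcpp::export]]
List cpp_sw_affine(NumericMatrix S, double gapOpen, double gapExtend) {
  int m = S.nrow(), n = S.ncol();
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix tM(m + 1, n + 1), tX(m + 1, n + 1), tY(m + 1, n + 1);

  for (int i = 0; i <= m; ++i) { X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF; }
  for (int j = 0; j <= n; ++j) { X(0, j) = NEG_INF; Y(0, j) = NEG_INF; }

  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M holds the best local alignment ending with pair (i, j); a value of
      // "start" (3) opens a fresh alignment at this pair
      double bm = 0.0; int sm = 3;
      if (M(i - 1, j - 1) > bm) { bm = M(i - 1, j - 1); sm = 0; }
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); sm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); sm = 2; }
      M(i, j) = bm + S(i - 1, j - 1); tM(i, j) = sm;

      double bx = M(i - 1, j) - (gapOpen + gapExtend); int sx = 0;
      if (X(i - 1, j) - gapExtend > bx) { bx = X(i - 1, j) - gapExtend; sx = 1; }
      if (Y(i - 1, j) - (gapOpen + gapExtend) > bx) { bx = Y(i - 1, j) - (gapOpen + gapExtend); sx = 2; }
      X(i, j) = bx; tX(i, j) = sx;

      double by = M(i, j - 1) - (gapOpen + gapExtend); int sy = 0;
      if (X(i, j - 1) - (gapOpen + gapExtend) > by) { by = X(i, j - 1) - (gapOpen + gapExtend); sy = 1; }
      if (Y(i, j - 1) - gapExtend > by) { by = Y(i, j - 1) - gapExtend; sy = 2; }
      Y(i, j) = by; tY(i, j) = sy;

      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  if (best <= 0.0 || bi < 0) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }

  // traceback from the best pair cell until an alignment start
  std::vector<int> qpos, ppos;
  int i = bi, j = bj, state = 0;
  while (true) {
    if (state == 0) {
      qpos.push_back(i); ppos.push_back(j);
      int prev = tM(i, j);
      --i; --j;
      if (prev == 3) break;
      state = prev;
    } else if (state == 1) {
      state = tX(i, j); --i;
    } else {
      state = tY(i, j); --j;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(ppos.begin(), ppos.end());
  return List::create(_["score"] = best, _["found"] = true,
                      _["qstart"] = qpos.front(), _["qend"] = bi,
                      _["pstart"] = ppos.front(), _["pend"] = bj,
                      _["qpos"] = IntegerVector(qpos.begin(), qpos.end()),
                      _["ppos"] = IntegerVector(ppos.begin(), ppos.end()));
}
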