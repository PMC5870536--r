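#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of a query sequence against a
// fixed column profile with affine gap costs. `score` is an n_cols x n_res
// matrix of per-column scores for each residue index; `query` holds 0-based
// residue indices (or -1 for symbols with no profile score, which get score
// 0 everywhere). Returns, for each profile column, the 1-based query index
// aligned to it, or 0 if the column is deleted in the query. Query residues
// not assigned to any column are insertions relative to the profile.
//
// States: M = query residue in column, X = query insertion (residue, no
// column), Y = column deletion (column, no residue).
// [[Rcpp::export]]
IntegerVector profile_align_c(NumericMatrix score, IntegerVector query,
                              double gap_open, double gap_extend) {
  const int P = score.nrow();   // profile columns
  const int L = query.size();   // query length
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<double> M((L + 1) * (P + 1), NEG), X = M, Y = M;
  std::vector<signed char> tbM(M.size(), 0), tbX(M.size(), 0), tbY(M.size(), 0);
  auto at = [P](int i, int j) { return i * (P + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= L; ++i) {
    X[at(i, 0)] = -gap_open - (i - 1) * gap_extend;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;  // 0: from M, 1: from X
  }
  for (int j = 1; j <= P; ++j) {
    Y[at(0, j)] = -gap_open - (j - 1) * gap_extend;
    tbY[at(0, j)] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= P; ++j) {
      const int q = query[i - 1];
      const double s = (q >= 0) ? score(j - 1, q) : 0.0;
      // M: diagonal from best of M/X/Y
      double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
             y0 = Y[at(i - 1, j - 1)];
      double best = m0; signed char tb = 0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M[at(i, j)] = (best == NEG) ? NEG : best + s;
      tbM[at(i, j)] = tb;
      // X: consume query residue i
      double xo = M[at(i - 1, j)] - gap_open;
      double xe = X[at(i - 1, j)] - gap_extend;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
      // Y: consume profile column j
      double yo = M[at(i, j - 1)] - gap_open;
      double ye = Y[at(i, j - 1)] - gap_extend;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 1; }
    }
  }

  // Traceback from the best terminal state.
  int state = 0;
  double best = M[at(L, P)];
  if (X[at(L, P)] > best) { best = X[at(L, P)]; state = 1; }
  if (Y[at(L, P)] > best) { best = Y[at(L, P)]; state = 2; }

  IntegerVector out(P, 0);
  int i = L, j = P;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char tb = tbM[at(i, j)];
      out[j - 1] = i;
      --i; --j;
      state = tb;
    } else if (state == 1) {
      signed char tb = tbX[at(i, j)];
      --i;
      state = (tb == 1) ? 1 : 0;
    } else {
      signed char tb = tbY[at(i, j)];
      --j;
      state = (tb == 1) ? 2 : 0;
    }
  }
  return out;
}
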