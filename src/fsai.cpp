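#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Access A[r, c] of a symmetric CSC matrix (column-sorted row indices) by
// binary search in column c.
static inline double get_entry(const int *Ap, const int *Ai, const double *Ax,
                               int r, int c) {
  const int lo = Ap[c], hi = Ap[c + 1];
  const int *first = std::lower_bound(Ai + lo, Ai + hi, r);
  if (first != Ai + hi && *first == r) return Ax[first - Ai];
  return 0.0;
}

// Solve the small dense system M y = e_last in place (partial pivoting).
// Returns false on (numerical) singularity.
static bool solve_small(std::vector<double> &M, std::vector<double> &y, int k) {
  std::fill(y.begin(), y.begin() + k, 0.0);
  y[k - 1] = 1.0;
  for (int col = 0; col < k; ++col) {
    int piv = col;
    double best = std::fabs(M[col * k + col]);
    for (int r = col + 1; r < k; ++r) {
      double v = std::fabs(M[col * k + r]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int c2 = 0; c2 < k; ++c2) std::swap(M[c2 * k + col], M[c2 * k + piv]);
      std::swap(y[col], y[piv]);
    }
    const double d = M[col * k + col];
    for (int r = col + 1; r < k; ++r) {
      const double f = M[col * k + r] / d;
      if (f == 0.0) continue;
      for (int c2 = col; c2 < k; ++c2) M[c2 * k + r] -= f * M[c2 * k + col];
      y[r] -= f * y[col];
    }
  }
  for (int col = k - 1; col >= 0; --col) {
    double s = y[col];
    for (int c2 = col + 1; c2 < k; ++c2) s -= M[c2 * k + col] * y[c2];
    y[col] = s / M[col * k + col];
  }
  return true;
}

// FSAI factor G (lower triangular, M^-1 = G'G ~= A^-1) for a symmetric
// positive definite CSC matrix. For each row i a small index set P_i
// (always containing i) is chosen from the lower-triangular row pattern:
//   pattern 0 ("bicgstab3"): three largest |A_ij|, j <= i
//   pattern 1 ("pcg_diag4"):  diagonal plus four largest |A_ij|, j < i
//   pattern 2 ("full_lower"): every stored j <= i
// Ties broken toward the smaller column index. The row of G is
// y / sqrt(y_last) where A[P,P] y = e_last. Singular local systems drop to
// the diagonal-only row (counted in `fallbacks`).
// [[Rcpp::export]]
List fsai_build(IntegerVector Ap_, IntegerVector Ai_, NumericVector Ax_,
                int n, int pattern) {
  const int *Ap = Ap_.begin();
  const int *Ai = Ai_.begin();
  const double *Ax = Ax_.begin();

  std::vector<int> out_i, out_j;
  std::vector<double> out_x;
  out_i.reserve(6 * (size_t)n);
  out_j.reserve(6 * (size_t)n);
  out_x.reserve(6 * (size_t)n);

  // lower-triangular row i of symmetric A == entries (row<=i) of column i
  std::vector<int> cols;
  std::vector<double> vals;
  std::vector<int> P;
  std::vector<double> M, y;
  int fallbacks = 0;

  for (int i = 0; i < n; ++i) {
    cols.clear(); vals.clear();
    for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
      if (Ai[k] <= i) { cols.push_back(Ai[k]); vals.push_back(Ax[k]); }
    }
    // choose pattern
    P.clear();
    const int m = (int)cols.size();
    std::vector<int> ord(m);
    for (int k = 0; k < m; ++k) ord[k] = k;
    if (pattern == 2) {
      // complete lower triangle: every column 0..i (exact inverse-Cholesky)
      for (int c2 = 0; c2 <= i; ++c2) P.push_back(c2);
    } else {
      int keep = (pattern == 0) ? 3 : 4;
      bool exclude_diag = (pattern == 1);
      std::vector<int> cand;
      for (int k = 0; k < m; ++k)
        if (!(exclude_diag && cols[k] == i)) cand.push_back(k);
      std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
        double va = std::fabs(vals[a]), vb = std::fabs(vals[b]);
        if (va != vb) return va > vb;
        return cols[a] < cols[b];
      });
      if ((int)cand.size() > keep) cand.resize(keep);
      for (int k : cand) P.push_back(cols[k]);
      // diagonal always forced into the set
      if (std::find(P.begin(), P.end(), i) == P.end()) P.push_back(i);
    }
    std::sort(P.begin(), P.end());
    const int k = (int)P.size();
    // local dense A[P,P] (column-major)
    M.assign((size_t)k * k, 0.0);
    y.resize(k);
    for (int c2 = 0; c2 < k; ++c2)
      for (int r = 0; r < k; ++r) {
        int a = P[r], b = P[c2];
        int rr = std::min(a, b), cc = std::max(a, b);
        M[(size_t)c2 * k + r] = get_entry(Ap, Ai, Ax, rr, cc);
      }
    bool ok = solve_small(M, y, k);
    double ylast = ok ? y[k - 1] : -1.0;
    if (!ok || ylast <= 0.0) {
      ++fallbacks;
      double d = get_entry(Ap, Ai, Ax, i, i);
      out_i.push_back(i); out_j.push_back(i);
      out_x.push_back(d > 0 ? 1.0 / std::sqrt(d) : 1.0);
      continue;
    }
    const double s = 1.0 / std::sqrt(ylast);
    for (int t = 0; t < k; ++t) {
      if (y[t] == 0.0) continue;
      out_i.push_back(i); out_j.push_back(P[t]); out_x.push_back(y[t] * s);
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x), _["fallbacks"] = fallbacks);
}
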