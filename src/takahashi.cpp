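#include <Rcpp.h>
using namespace Rcpp;

// Binary search for row r within [lo, hi) of the sorted row-index array.
// Returns the index into i/x arrays, or -1 if the position is not present.
static inline R_xlen_t find_pos(const int *Li, R_xlen_t lo, R_xlen_t hi, int r) {
  R_xlen_t end = hi;
  while (lo < hi) {
    R_xlen_t mid = lo + (hi - lo) / 2;
    if (Li[mid] < r) lo = mid + 1; else hi = mid;
  }
  if (lo < end && Li[lo] == r) return lo;
  return -1;
}

//' @noRd
// [[Rcpp::export(name = ".takahashi_inverse")]]
NumericVector takahashi_inverse(IntegerVector Lp, IntegerVector Li,
                                NumericVector Lx, int n) {
  // Sparse inverse subset (Takahashi / Erisman-Tinney recursion) on the
  // pattern of a lower-triangular Cholesky factor L, where C = L L'.
  // Row indices must be sorted within columns with the diagonal first.
  // Returns values of C^{-1} at the positions of pattern(L).
  const int *lp = Lp.begin();
  const int *li = Li.begin();
  const double *lx = Lx.begin();
  R_xlen_t nnz = Lx.size();
  NumericVector Sout(nnz);
  double *S = Sout.begin();

  // unit factor and D: C = Lu D Lu' with Lu[k,j] = L[k,j]/L[j,j], d_j = L[j,j]^2
  std::vector<double> Lu(nnz), dinv(n);
  for (int j = 0; j < n; ++j) {
    R_xlen_t pj = lp[j];
    if (pj >= lp[j + 1] || li[pj] != j)
      stop("factor column %d lacks a leading diagonal entry", j + 1);
    double ljj = lx[pj];
    dinv[j] = 1.0 / (ljj * ljj);
    for (R_xlen_t p = pj; p < lp[j + 1]; ++p) Lu[p] = lx[p] / ljj;
  }

  for (int j = n - 1; j >= 0; --j) {
    R_xlen_t p0 = lp[j], p1 = lp[j + 1];
    // off-diagonals: S[i,j] = -sum_{k>j in col j} Lu[k,j] * S[max(i,k),min(i,k)]
    for (R_xlen_t p = p0 + 1; p < p1; ++p) {
      int i = li[p];
      double acc = 0.0;
      for (R_xlen_t q = p0 + 1; q < p1; ++q) {
        int k = li[q];
        double skj;
        if (k == i) {
          // S[i,i]: diagonal of column i (> j), already computed
          skj = S[lp[i]];
        } else {
          int c = k < i ? k : i;
          int r = k < i ? i : k;
          R_xlen_t pos = find_pos(li, lp[c], lp[c + 1], r);
          if (pos < 0)
            stop("inverse-subset pattern closure violated at (%d,%d)", r + 1, c + 1);
          skj = S[pos];
        }
        acc += Lu[q] * skj;
      }
      S[p] = -acc;
    }
    // diagonal: S[j,j] = 1/d_j - sum_{k>j} Lu[k,j] * S[k,j]
    double acc = 0.0;
    for (R_xlen_t p = p0 + 1; p < p1; ++p) acc += Lu[p] * S[p];
    S[p0] = dinv[j] - acc;
  }
  return Sout;
}

//' @noRd
// [[Rcpp::export(name = ".cinv_gather")]]
NumericVector cinv_gather(IntegerVector Lp, IntegerVector Li, NumericVector Sx,
                          IntegerVector invperm, IntegerVector rows,
                          IntegerVector cols) {
  // Gather C^{-1}[rows[t], cols[t]] (1-based, original ordering) from the
  // inverse subset Sx stored on the permuted factor pattern.
  // invperm maps original index (1-based) -> permuted index (0-based).
  R_xlen_t m = rows.size();
  if (cols.size() != m) stop("rows/cols length mismatch");
  NumericVector out(m);
  const int *lp = Lp.begin();
  const int *li = Li.begin();
  const double *sx = Sx.begin();
  const int *ip = invperm.begin();
  for (R_xlen_t t = 0; t < m; ++t) {
    int a = ip[rows[t] - 1], b = ip[cols[t] - 1];
    int c = a < b ? a : b;
    int r = a < b ? b : a;
    R_xlen_t pos = find_pos(li, lp[c], lp[c + 1], r);
    if (pos < 0)
      stop("requested element (%d,%d) lies outside the factor pattern",
           rows[t], cols[t]);
    out[t] = sx[pos];
  }
  return out;
}
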