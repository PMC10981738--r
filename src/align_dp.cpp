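#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment over a precomputed substitution matrix S
// (query residues x target residues) with a linear gap penalty.  Traceback
// precedence is diagonal > up > left; coordinates in the returned pair
// list are 0-based.

// [[Rcpp::export]]
List nw_align_cpp(NumericMatrix S, double gap) {
  const int m = S.nrow(), n = S.ncol();
  if (m == 0 || n == 0) stop("empty substitution matrix");
  NumericMatrix H(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) H(i, 0) = -gap * i;
  for (int j = 0; j <= n; ++j) H(0, j) = -gap * j;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double up = H(i - 1, j) - gap;
      double left = H(i, j - 1) - gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      H(i, j) = best;
    }
  }
  // traceback
  std::vector<int> qi, ti;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && H(i, j) == H(i - 1, j - 1) + S(i - 1, j - 1)) {
      qi.push_back(i - 1); ti.push_back(j - 1); --i; --j;
    } else if (i > 0 && H(i, j) == H(i - 1, j) - gap) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ti.begin(), ti.end());
  return List::create(_["score"] = H(m, n),
                      _["query_index"] = wrap(qi),
                      _["target_index"] = wrap(ti));
}

// [[Rcpp::export]]
List sw_align_cpp(NumericMatrix S, double gap) {
  const int m = S.nrow(), n = S.ncol();
  if (m == 0 || n == 0) stop("empty substitution matrix");
  NumericMatrix H(m + 1, n + 1);   // zero-initialized
  double best = 0.0;
  int bi = 0, bj = 0;              // best cell; ties keep smallest (i, j)
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double v = H(i - 1, j - 1) + S(i - 1, j - 1);
      double up = H(i - 1, j) - gap;
      double left = H(i, j - 1) - gap;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      H(i, j) = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::vector<int> qi, ti;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H(i, j) > 0.0) {
    if (H(i, j) == H(i - 1, j - 1) + S(i - 1, j - 1)) {
      qi.push_back(i - 1); ti.push_back(j - 1); --i; --j;
    } else if (H(i, j) == H(i - 1, j) - gap) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ti.begin(), ti.end());
  return List::create(_["score"] = best,
                      _["query_index"] = wrap(qi),
                      _["target_index"] = wrap(ti));
}
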