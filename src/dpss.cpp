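// Top-k eigenpairs of a symmetric tridiagonal matrix by Sturm-sequence
// bisection plus inverse iteration (the dstebz/dstein strategy). Used for
// Slepian (DPSS) tapers, whose defining matrix is tridiagonal; avoids the
// O(n^2) memory of a dense eigendecomposition for long windows.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// number of eigenvalues of tridiag(d, e) strictly below x
static int sturm_count(const NumericVector& d, const NumericVector& e,
                       double x) {
  int n = d.size(), count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    double denom = (q == 0.0) ? 1e-300 : q;
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q < 0) ++count;
  }
  return count;
}

// solve (T - mu I) v = w for tridiagonal T, Gaussian elimination with
// partial pivoting (bandwidth grows to 2 above the diagonal)
static void tridiag_solve(const NumericVector& d, const NumericVector& e,
                          double mu, std::vector<double>& v) {
  int n = d.size();
  std::vector<double> a(n), b(n - 1), c(n - 1), f(n > 2 ? n - 2 : 0, 0.0);
  for (int i = 0; i < n; ++i) a[i] = d[i] - mu;
  for (int i = 0; i < n - 1; ++i) { b[i] = e[i]; c[i] = e[i]; }
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(c[i]) > std::fabs(a[i])) {   // pivot rows i, i+1
      std::swap(a[i], c[i]);
      double bi = b[i];
      b[i] = a[i + 1]; a[i + 1] = bi;
      if (i < n - 2) { f[i] = b[i + 1]; b[i + 1] = 0.0; }
      std::swap(v[i], v[i + 1]);
    }
    if (a[i] == 0.0) a[i] = 1e-300;
    double m = c[i] / a[i];
    a[i + 1] -= m * b[i];
    if (i < n - 2) b[i + 1] -= m * f[i];
    v[i + 1] -= m * v[i];
  }
  if (a[n - 1] == 0.0) a[n - 1] = 1e-300;
  v[n - 1] /= a[n - 1];
  if (n >= 2) v[n - 2] = (v[n - 2] - b[n - 2] * v[n - 1]) / a[n - 2];
  for (int i = n - 3; i >= 0; --i)
    v[i] = (v[i] - b[i] * v[i + 1] - f[i] * v[i + 2]) / a[i];
}

// [[Rcpp::export]]
List tridiag_topk_eigen(NumericVector d, NumericVector e, int k) {
  int n = d.size();
  if (k < 1 || k > n) stop("k out of range");
  // Gershgorin bounds
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double r = (i > 0 ? std::fabs(e[i - 1]) : 0.0) +
               (i < n - 1 ? std::fabs(e[i]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  double span = hi - lo;
  NumericVector vals(k);
  NumericMatrix vecs(n, k);
  for (int j = 0; j < k; ++j) {
    int target = n - 1 - j;                 // j-th largest, 0-based
    double a = lo, b = hi + 1e-8 * span;
    for (int it = 0; it < 200 && (b - a) > 1e-14 * span; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) <= target) a = mid; else b = mid;
    }
    double lambda = 0.5 * (a + b);
    vals[j] = lambda;
    // inverse iteration with Gram-Schmidt against previous vectors
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i)
      v[i] = std::sin((j + 1.0) * M_PI * (i + 1.0) / (n + 1.0)) + 1e-3 * ((i * 2654435761u) % 1000 / 1000.0 - 0.5);
    for (int it = 0; it < 5; ++it) {
      tridiag_solve(d, e, lambda + 1e-12 * span, v);
      for (int p = 0; p < j; ++p) {
        double dot = 0;
        for (int i = 0; i < n; ++i) dot += v[i] * vecs(i, p);
        for (int i = 0; i < n; ++i) v[i] -= dot * vecs(i, p);
      }
      double nrm = 0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      if (nrm == 0) stop("inverse iteration broke down");
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    for (int i = 0; i < n; ++i) vecs(i, j) = v[i];
  }
  return List::create(_["values"] = vals, _["vectors"] = vecs);
}
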