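// Sequential minimal optimization (simplified SMO) for a soft-margin
// kernel SVM dual. The second working index is drawn from R's RNG, so a
// caller-side seed makes training reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C, double tol,
               int max_passes, int max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  double b = 0.0;
  int passes = 0, iter = 0;
  GetRNGstate();
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = f[i] + b - y[i];
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0))) continue;
      int j = (int)(unif_rand() * (n - 1));
      if (j >= i) ++j;
      if (j >= n) j = n - 1;
      double Ej = f[j] + b - y[j];
      double ai_old = alpha[i], aj_old = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(C, C + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - C);
        H = std::min(C, ai_old + aj_old);
      }
      if (L >= H) continue;
      double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
      if (eta >= 0) continue;
      double aj = aj_old - y[j] * (Ei - Ej) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-7) continue;
      double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      double dai = ai - ai_old, daj = aj - aj_old;
      for (int t = 0; t < n; ++t)
        f[t] += dai * y[i] * K(t, i) + daj * y[j] * K(t, j);
      double b1 = b - Ei - y[i] * dai * K(i, i) - y[j] * daj * K(i, j);
      double b2 = b - Ej - y[i] * dai * K(i, j) - y[j] * daj * K(j, j);
      if (ai > 0 && ai < C) b = b1;
      else if (aj > 0 && aj < C) b = b2;
      else b = 0.5 * (b1 + b2);
      alpha[i] = ai; alpha[j] = aj;
      ++changed;
    }
    passes = (changed == 0) ? passes + 1 : 0;
    ++iter;
  }
  PutRNGstate();
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}
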