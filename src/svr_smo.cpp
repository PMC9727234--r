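// Epsilon-SVR dual solver (libsvm-style SMO, first-order working-set
// selection). Solves, over t in [0, C]^{2n} with signs s = (+1^n, -1^n):
//   min 0.5 t' Q t + p' t   s.t.  s' t = 0,
// where Q_{ab} = s_a s_b K_{d(a) d(b)}, p = (eps - y, eps + y).
// beta_i = t_i - t_{n+i} are the usual SVR coefficients and
// f(x) = sum_i beta_i K(x_i, x) + b.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List svr_smo(NumericMatrix K, NumericVector y, double C, double eps,
             double tol = 1e-3, int max_iter = 100000) {
  const int n = y.size();
  const int m = 2 * n;
  std::vector<double> t(m, 0.0), G(m), p(m);
  std::vector<int> sgn(m), didx(m);
  for (int i = 0; i < n; ++i) {
    p[i] = eps - y[i];     sgn[i] = 1;      didx[i] = i;
    p[n + i] = eps + y[i]; sgn[n + i] = -1; didx[n + i] = i;
  }
  for (int a = 0; a < m; ++a) G[a] = p[a];

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working set: i maximizes -s G over I_up, j minimizes over I_low
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int a = 0; a < m; ++a) {
      bool in_up = (sgn[a] == 1) ? (t[a] < C) : (t[a] > 0.0);
      bool in_low = (sgn[a] == 1) ? (t[a] > 0.0) : (t[a] < C);
      double v = -sgn[a] * G[a];
      if (in_up && v > gmax) { gmax = v; i = a; }
      if (in_low && v < gmin) { gmin = v; j = a; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    int di = didx[i], dj = didx[j];
    double a2 = K(di, di) + K(dj, dj) - 2.0 * K(di, dj);
    if (a2 <= 0) a2 = 1e-12;
    double lambda = (gmax - gmin) / a2;
    // box clipping
    double max_i = (sgn[i] == 1) ? (C - t[i]) : t[i];
    double max_j = (sgn[j] == 1) ? t[j] : (C - t[j]);
    if (lambda > max_i) lambda = max_i;
    if (lambda > max_j) lambda = max_j;
    if (lambda <= 0) break;
    t[i] += sgn[i] * lambda;
    t[j] -= sgn[j] * lambda;
    // gradient update: G_a += s_a * lambda * (K[da,di] - K[da,dj])
    for (int a = 0; a < m; ++a)
      G[a] += sgn[a] * lambda * (K(didx[a], di) - K(didx[a], dj));
  }

  // bias from KKT: average -s G over free variables, else midpoint of bounds
  double sum_free = 0.0; int n_free = 0;
  double ub = 1e300, lb = -1e300;
  for (int a = 0; a < m; ++a) {
    double v = -sgn[a] * G[a];
    bool in_up = (sgn[a] == 1) ? (t[a] < C) : (t[a] > 0.0);
    bool in_low = (sgn[a] == 1) ? (t[a] > 0.0) : (t[a] < C);
    if (in_up && in_low) { sum_free += v; ++n_free; }
    else if (in_up) { if (v < ub) ub = v; }
    else if (in_low) { if (v > lb) lb = v; }
  }
  double b = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;

  NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = t[i] - t[n + i];
  return List::create(_["beta"] = beta, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
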