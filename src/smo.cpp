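#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Sequential minimal optimisation for the box-and-equality-constrained QP
//
//   min_a  0.5 a' Q a + p' a   s.t.  y' a = 0,  0 <= a_i <= C_i,
//
// with y_i in {-1, +1}. Working-set selection is the maximal violating
// pair; the same routine serves the soft-margin classification dual
// (Q_ij = y_i y_j K_ij, p = -1) and the epsilon-insensitive regression
// dual in its doubled 2n-variable form. Termination: KKT violation
// m(a) - M(a) < tol.
//
// Returns alpha, the offset rho (decision function bias is -rho), the
// objective value, iteration count, and the final KKT violation.

// [[Rcpp::export]]
List smo_solve(NumericMatrix Q, NumericVector p, IntegerVector y,
               NumericVector C, double tol, int max_iter,
               Nullable<NumericVector> alpha0 = R_NilValue) {
  const int n = Q.nrow();
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(p.begin(), p.end());
  if (alpha0.isNotNull()) {
    NumericVector a0(alpha0);
    if (a0.size() == n) {
      // warm start from a feasible point: G = p + Q a0
      for (int i = 0; i < n; ++i) alpha[i] = a0[i];
      for (int j = 0; j < n; ++j) {
        if (alpha[j] == 0.0) continue;
        const double aj = alpha[j];
        for (int i = 0; i < n; ++i) G[i] += aj * Q(i, j);
      }
    }
  }

  std::vector<double> qd(n);
  for (int t = 0; t < n; ++t) qd[t] = Q(t, t);

  int iter = 0;
  double m_val = 0.0, M_val = 0.0;
  while (iter < max_iter) {
    // first-order choice of i; second-order (maximal decrease) choice of j
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] == 1) ? (alpha[t] < C[t]) : (alpha[t] > 0.0);
      const double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
    }
    double best_dec = 0.0;
    if (i >= 0) {
      const double *qi = &Q(0, i);   // column i == row i (Q symmetric)
      const double qii = qd[i];
      for (int t = 0; t < n; ++t) {
        const bool low = (y[t] == 1) ? (alpha[t] > 0.0)
                                     : (alpha[t] < C[t]);
        if (!low) continue;
        const double v = -y[t] * G[t];
        if (v < Gmin) Gmin = v;
        if (v < Gmax) {
          const double diff = Gmax - v;
          double a = qii + qd[t] - 2.0 * y[i] * y[t] * qi[t];
          if (a <= 0.0) a = TAU;
          const double dec = diff * diff / a;
          if (dec > best_dec) { best_dec = dec; j = t; }
        }
      }
    }
    m_val = (i >= 0) ? Gmax : 0.0;
    M_val = std::isfinite(Gmin) ? Gmin : 0.0;
    if (i < 0 || j < 0 || m_val - M_val < tol) break;

    double a = Q(i, i) + Q(j, j) - 2.0 * y[i] * y[j] * Q(i, j);
    if (a <= 0.0) a = TAU;
    double step = (-y[i] * G[i] + y[j] * G[j]) / a;
    const double bound_i = (y[i] == 1) ? (C[i] - alpha[i]) : alpha[i];
    const double bound_j = (y[j] == 1) ? alpha[j] : (C[j] - alpha[j]);
    if (step > bound_i) step = bound_i;
    if (step > bound_j) step = bound_j;

    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    for (int t = 0; t < n; ++t)
      G[t] += step * (y[i] * Q(t, i) - y[j] * Q(t, j));
    ++iter;
  }

  // rho: mean of y_i G_i over free variables, midpoint fallback
  double sfree = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C[t] - 1e-12) {
      sfree += y[t] * G[t];
      ++nfree;
    }
  }
  const double rho = (nfree > 0) ? sfree / nfree : -(m_val + M_val) / 2.0;

  // objective: G = Q a + p  =>  0.5 a'(G + p) = 0.5 a'Qa + p'a
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += 0.5 * alpha[t] * (G[t] + p[t]);

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["rho"] = rho, _["obj"] = obj, _["iterations"] = iter,
    _["violation"] = m_val - M_val,
    _["converged"] = (m_val - M_val) < tol);
}
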