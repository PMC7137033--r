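#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Sequential minimal optimisation for the C-SVC dual on a precomputed
// kernel matrix:
//
//   min_a  1/2 a' Q a - e' a,   0 <= a_i <= C,  y' a = 0,   Q_ij = y_i y_j K_ij
//
// Working-set selection is the first-order maximal-violating-pair rule
// (Keerthi et al. 2001); convergence when m(a) - M(a) < tol.  The decision
// function of the fitted machine is f(x) = sum_i a_i y_i K(x_i, x) - rho.
//
// Solving the dual ourselves (rather than binding a library) keeps the
// package dependency-free; correctness is pinned by tests against the dual
// KKT conditions and a quadratic-programming oracle.

// [[Rcpp::export]]
List cpp_smo(const NumericMatrix& K, const NumericVector& y, double C,
             double tol, int max_iter, Nullable<NumericVector> alpha0 = R_NilValue) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("K must be square");
  if (y.size() != n) stop("length(y) != nrow(K)");

  const double TAU = 1e-12;
  std::vector<double> a(n, 0.0), G(n, -1.0);

  if (alpha0.isNotNull()) {
    NumericVector a0(alpha0);
    if (a0.size() != n) stop("alpha0 has wrong length");
    bool any = false;
    for (int i = 0; i < n; ++i) { a[i] = a0[i]; if (a[i] != 0.0) any = true; }
    if (any) {  // G = Qa - e
      for (int t = 0; t < n; ++t) {
        double s = 0.0;
        for (int j = 0; j < n; ++j)
          if (a[j] > 0.0) s += a[j] * y[j] * K(t, j);
        G[t] = y[t] * s - 1.0;
      }
    }
  }

  const double* Kp = K.begin();  // column-major, symmetric
  std::vector<double> Kdiag(n);
  for (int t = 0; t < n; ++t) Kdiag[t] = Kp[(size_t)t * n + t];

  int iter = 0;
  double m = 0.0, M = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // second-order working-set selection (WSS2 of Fan, Chen & Lin 2005):
    // i maximises the violation, j minimises the one-step objective gain
    int i = -1, j = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] > 0) ? (a[t] < C) : (a[t] > 0);
      if (up && v > m) { m = v; i = t; }
    }
    if (i < 0) break;
    const double* Ki = Kp + (size_t)i * n;  // column i == row i (symmetry)
    const double Kii = Kdiag[i], yi = y[i];
    double best = 0.0;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool low = (y[t] > 0) ? (a[t] > 0) : (a[t] < C);
      if (!low) continue;
      if (v < M) M = v;
      const double b = m - v;
      if (b > 0) {
        double qd = Kii + Kdiag[t] - 2.0 * yi * y[t] * Ki[t];
        if (qd <= 0) qd = TAU;
        const double gain = -(b * b) / qd;
        if (gain < best) { best = gain; j = t; }
      }
    }
    if (j < 0 || m - M < tol) break;

    const double ai_old = a[i], aj_old = a[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) { if (a[j] < 0) { a[j] = 0; a[i] = diff; } }
      else          { if (a[i] < 0) { a[i] = 0; a[j] = -diff; } }
      if (diff > 0) { if (a[i] > C) { a[i] = C; a[j] = C - diff; } }
      else          { if (a[j] > C) { a[j] = C; a[i] = C + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) { if (a[i] > C) { a[i] = C; a[j] = sum - C; } }
      else         { if (a[j] < 0) { a[j] = 0; a[i] = sum; } }
      if (sum > C) { if (a[j] > C) { a[j] = C; a[i] = sum - C; } }
      else         { if (a[i] < 0) { a[i] = 0; a[j] = sum; } }
    }

    const double dai = a[i] - ai_old, daj = a[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck pair
    const double ci = y[i] * dai, cj = y[j] * daj;
    const double* Kj = Kp + (size_t)j * n;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (Ki[t] * ci + Kj[t] * cj);
  }

  // rho: average y_t G_t over free vectors, else midpoint of the bounds
  double sum_free = 0.0, ub = std::numeric_limits<double>::infinity(),
         lb = -std::numeric_limits<double>::infinity();
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (a[t] >= C) {        // upper bound
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (a[t] <= 0) { // lower bound
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nfree; sum_free += yG; }
  }
  const double rho = nfree > 0 ? sum_free / nfree : (ub + lb) / 2.0;

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += a[t] * (G[t] - 1.0);
  obj /= 2.0;

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["converged"] = (m - M < tol), _["objective"] = obj);
}

// RBF kernel from a cross-Gram matrix and the row squared norms:
// K_ij = exp(-gamma * max(da_i + db_j - 2 G_ij, 0)).  One pass, no
// temporaries -- this sits inside the forward-search and grid-search loops.
// [[Rcpp::export]]
NumericMatrix cpp_rbf_kernel(const NumericMatrix& G, const NumericVector& da,
                             const NumericVector& db, double gamma) {
  const int n = G.nrow(), m = G.ncol();
  if (da.size() != n || db.size() != m) stop("norm vectors do not match G");
  NumericMatrix K(n, m);
  const double* gp = G.begin();
  double* kp = K.begin();
  for (int j = 0; j < m; ++j) {
    const double dbj = db[j];
    const double* gc = gp + (size_t)j * n;
    double* kc = kp + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double d2 = da[i] + dbj - 2.0 * gc[i];
      if (d2 < 0) d2 = 0;
      kc[i] = std::exp(-gamma * d2);
    }
  }
  return K;
}

// Squared-distance matrix from a cross-Gram matrix (same layout as above).
// [[Rcpp::export]]
NumericMatrix cpp_sqdist(const NumericMatrix& G, const NumericVector& da,
                         const NumericVector& db) {
  const int n = G.nrow(), m = G.ncol();
  if (da.size() != n || db.size() != m) stop("norm vectors do not match G");
  NumericMatrix D(n, m);
  for (int j = 0; j < m; ++j) {
    const double dbj = db[j];
    for (int i = 0; i < n; ++i) {
      double d2 = da[i] + dbj - 2.0 * G(i, j);
      D(i, j) = d2 < 0 ? 0 : d2;
    }
  }
  return D;
}
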