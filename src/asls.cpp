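#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Penalized asymmetric least-squares baseline.
// Solves (W + lam * D'D) z = W y with D the (n-2) x n second-difference
// operator.  The system matrix is symmetric pentadiagonal; an LDL'
// factorization with bandwidth 2 keeps the cost O(n) per iteration.

static void asls_one(const double *y, int n, double lam, double p, int n_iter,
                     double *z,
                     std::vector<double> &pen0, std::vector<double> &pen1,
                     std::vector<double> &pen2, std::vector<double> &w,
                     std::vector<double> &d, std::vector<double> &e,
                     std::vector<double> &f, std::vector<double> &v) {
  std::fill(w.begin(), w.begin() + n, 1.0);
  for (int iter = 0; iter < n_iter; ++iter) {
    // factor M = L D L', L unit lower-triangular with bands e (sub-1), f (sub-2)
    for (int i = 0; i < n; ++i) {
      double fi = 0.0, ei = 0.0;
      if (i >= 2) fi = pen2[i - 2] / d[i - 2];
      if (i >= 1) {
        double a1 = pen1[i - 1];
        if (i >= 2) a1 -= fi * d[i - 2] * e[i - 1];
        ei = a1 / d[i - 1];
      }
      double di = pen0[i] + w[i];
      if (i >= 1) di -= ei * ei * d[i - 1];
      if (i >= 2) di -= fi * fi * d[i - 2];
      e[i] = ei;
      f[i] = fi;
      d[i] = di;
    }
    // forward substitution L v = W y
    for (int i = 0; i < n; ++i) {
      double vi = w[i] * y[i];
      if (i >= 1) vi -= e[i] * v[i - 1];
      if (i >= 2) vi -= f[i] * v[i - 2];
      v[i] = vi;
    }
    for (int i = 0; i < n; ++i) v[i] /= d[i];
    // back substitution L' z = v
    for (int i = n - 1; i >= 0; --i) {
      double zi = v[i];
      if (i + 1 < n) zi -= e[i + 1] * z[i + 1];
      if (i + 2 < n) zi -= f[i + 2] * z[i + 2];
      z[i] = zi;
    }
    // asymmetric reweighting: peaks (positive residuals) get weight p
    for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : 1.0 - p;
  }
}

static void build_penalty(int n, double lam, std::vector<double> &pen0,
                          std::vector<double> &pen1, std::vector<double> &pen2) {
  std::fill(pen0.begin(), pen0.begin() + n, 0.0);
  std::fill(pen1.begin(), pen1.begin() + n, 0.0);
  std::fill(pen2.begin(), pen2.begin() + n, 0.0);
  for (int k = 0; k + 2 < n; ++k) {
    pen0[k] += lam;
    pen0[k + 1] += 4.0 * lam;
    pen0[k + 2] += lam;
    pen1[k] += -2.0 * lam;
    pen1[k + 1] += -2.0 * lam;
    pen2[k] += lam;
  }
}

// [[Rcpp::export]]
NumericVector asls_cpp(NumericVector y, double lam, double p, int n_iter) {
  int n = y.size();
  if (n < 3) stop("AsLS needs at least 3 channels");
  std::vector<double> pen0(n), pen1(n), pen2(n), w(n), d(n), e(n), f(n), v(n);
  build_penalty(n, lam, pen0, pen1, pen2);
  NumericVector z(n);
  asls_one(&y[0], n, lam, p, n_iter, &z[0], pen0, pen1, pen2, w, d, e, f, v);
  return z;
}

// [[Rcpp::export]]
NumericMatrix asls_mat_cpp(NumericMatrix Y, double lam, double p, int n_iter) {
  int nr = Y.nrow(), n = Y.ncol();
  if (n < 3) stop("AsLS needs at least 3 channels");
  std::vector<double> pen0(n), pen1(n), pen2(n), w(n), d(n), e(n), f(n), v(n);
  build_penalty(n, lam, pen0, pen1, pen2);
  NumericMatrix Z(nr, n);
  std::vector<double> yi(n), zi(n);
  for (int r = 0; r < nr; ++r) {
    for (int j = 0; j < n; ++j) yi[j] = Y(r, j);
    asls_one(yi.data(), n, lam, p, n_iter, zi.data(), pen0, pen1, pen2, w, d,
             e, f, v);
    for (int j = 0; j < n; ++j) Z(r, j) = zi[j];
  }
  return Z;
}
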