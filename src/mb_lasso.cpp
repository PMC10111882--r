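#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Covariance-form coordinate descent for the lasso:
//   min_b 0.5 * b' S[-j,-j] b - S[-j,j]' b + lambda * ||b||_1
// solved along a decreasing lambda path with warm starts and an
// incrementally maintained gradient, as in neighborhood-selection graph
// estimators. S is the (p x p) correlation/covariance matrix of the
// CLR-transformed data; node j's neighborhood is the support of b.

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// solve the path for one node; beta is (p) with beta[j] fixed at 0
static void node_path(const double* S, int p, int j,
                      const NumericVector& lambdas,
                      double tol, int maxit,
                      std::vector<double>& beta,
                      std::vector<double>& g,
                      unsigned char* support, R_xlen_t stride) {
  const int nlam = lambdas.size();
  std::fill(beta.begin(), beta.end(), 0.0);
  for (int k = 0; k < p; ++k) g[k] = S[(R_xlen_t)j * p + k];
  for (int m = 0; m < nlam; ++m) {
    const double lam = lambdas[m];
    for (int it = 0; it < maxit; ++it) {
      double max_change = 0.0;
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        const double skk = S[(R_xlen_t)k * p + k];
        const double z = g[k] + skk * beta[k];
        const double bnew = soft(z, lam) / skk;
        const double d = bnew - beta[k];
        if (std::fabs(d) > 1e-14) {
          beta[k] = bnew;
          const double* Sk = S + (R_xlen_t)k * p;
          for (int l = 0; l < p; ++l) g[l] -= Sk[l] * d;
          if (std::fabs(d) > max_change) max_change = std::fabs(d);
        }
      }
      if (max_change < tol) break;
    }
    unsigned char* out = support + (R_xlen_t)m * stride;
    for (int k = 0; k < p; ++k)
      if (k != j && beta[k] != 0.0) out[(R_xlen_t)j * p + k] = 1;
  }
}

// [[Rcpp::export]]
NumericMatrix lasso_path_node_cpp(NumericMatrix S, int j, NumericVector lambdas,
                                  double tol = 1e-10, int maxit = 10000) {
  const int p = S.nrow();
  const int nlam = lambdas.size();
  if (j < 1 || j > p) stop("node index out of range");
  std::vector<double> beta(p, 0.0), g(p, 0.0);
  NumericMatrix out(p, nlam);
  const double* Sp = REAL(S);
  const int jj = j - 1;
  std::fill(beta.begin(), beta.end(), 0.0);
  for (int k = 0; k < p; ++k) g[k] = Sp[(R_xlen_t)jj * p + k];
  for (int m = 0; m < nlam; ++m) {
    const double lam = lambdas[m];
    for (int it = 0; it < maxit; ++it) {
      double max_change = 0.0;
      for (int k = 0; k < p; ++k) {
        if (k == jj) continue;
        const double skk = Sp[(R_xlen_t)k * p + k];
        const double z = g[k] + skk * beta[k];
        const double bnew = soft(z, lam) / skk;
        const double d = bnew - beta[k];
        if (std::fabs(d) != 0.0) {
          beta[k] = bnew;
          const double* Sk = Sp + (R_xlen_t)k * p;
          for (int l = 0; l < p; ++l) g[l] -= Sk[l] * d;
          if (std::fabs(d) > max_change) max_change = std::fabs(d);
        }
      }
      if (max_change < tol) break;
    }
    for (int k = 0; k < p; ++k) out(k, m) = beta[k];
  }
  return out;
}

// Edge support along the lambda path for all nodes.
// rule: 0 = OR symmetrisation, 1 = AND.
// Returns an integer matrix (p*(p-1)/2 rows in upper.tri column-major
// order, nlam columns) of 0/1 edge indicators.
// [[Rcpp::export]]
IntegerMatrix mb_support_cpp(NumericMatrix S, NumericVector lambdas,
                             int rule = 0, double tol = 1e-4,
                             int maxit = 50) {
  const int p = S.nrow();
  const int nlam = lambdas.size();
  const R_xlen_t stride = (R_xlen_t)p * p;
  std::vector<unsigned char> sel((R_xlen_t)nlam * stride, 0);
  std::vector<double> beta(p), g(p);
  const double* Sp = REAL(S);
  for (int j = 0; j < p; ++j)
    node_path(Sp, p, j, lambdas, tol, maxit, beta, g, sel.data(), stride);
  const int npair = p * (p - 1) / 2;
  IntegerMatrix out(npair, nlam);
  for (int m = 0; m < nlam; ++m) {
    const unsigned char* sm = sel.data() + (R_xlen_t)m * stride;
    int idx = 0;
    for (int k2 = 1; k2 < p; ++k2) {
      for (int k1 = 0; k1 < k2; ++k1, ++idx) {
        const bool a = sm[(R_xlen_t)k1 * p + k2] != 0; // k1's neighborhood has k2
        const bool b = sm[(R_xlen_t)k2 * p + k1] != 0;
        out(idx, m) = rule == 0 ? (a || b) : (a && b);
      }
    }
  }
  return out;
}
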