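#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft2(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent on an explicit quadratic model
//    f(b) = 0.5 b'Ab - c'b + l1 ||b||_1 + 0.5 l2 ||b||^2
// with A the (positive semi-definite) curvature matrix. Used as the
// proximal-Newton subproblem solver of the penalised Cox path, where A is
// the exact observed information divided by n. Maintains s = A b for O(p)
// coordinate updates, and interleaves full sweeps with sweeps over the
// currently nonzero coordinates (the usual active-set strategy).
// [[Rcpp::export(name = ".cd_quad_cpp")]]
NumericVector cd_quad_cpp(NumericMatrix A, NumericVector c, NumericVector beta,
                          double l1, double l2, int maxit, double tol) {
  const int p = A.ncol();
  NumericVector b = clone(beta);
  std::vector<double> s(p, 0.0);  // A b
  for (int j = 0; j < p; ++j)
    if (b[j] != 0.0)
      for (int i = 0; i < p; ++i) s[i] += A(i, j) * b[j];

  auto update = [&](int j) -> double {
    double ajj = A(j, j);
    if (ajj <= 0.0) return 0.0;
    double num = c[j] - (s[j] - ajj * b[j]);
    double bj = soft2(num, l1) / (ajj + l2);
    double del = bj - b[j];
    if (del != 0.0) {
      for (int i = 0; i < p; ++i) s[i] += A(i, j) * del;
      b[j] = bj;
      return std::fabs(del) * std::sqrt(ajj);
    }
    return 0.0;
  };

  int sweeps = 0;
  while (sweeps < maxit) {
    ++sweeps;
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      double d = update(j);
      if (d > maxdel) maxdel = d;
    }
    if (maxdel < tol) break;
    std::vector<int> active;
    active.reserve(p);
    for (int j = 0; j < p; ++j) if (b[j] != 0.0) active.push_back(j);
    while (sweeps < maxit) {
      ++sweeps;
      double amax = 0.0;
      for (int j : active) {
        double d = update(j);
        if (d > amax) amax = d;
      }
      if (amax < tol) break;
    }
  }
  return b;
}
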