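#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Log partial likelihood, score and (optionally) second-derivative matrix of
// a Cox model, with Efron or Breslow handling of tied event times.
//
// Rows must be pre-sorted by time DESCENDING so the risk set at an event time
// is a prefix. A single pass accumulates the weighted sums S0, S1, S2 over
// the risk set; at the end of each tied-time block the within-block event
// sums feed the Efron correction loop.
// [[Rcpp::export(name = ".cox_deriv_cpp")]]
List cox_deriv_cpp(NumericMatrix X, NumericVector eta, IntegerVector event,
                   NumericVector time, bool efron, bool hessian) {
  const int n = X.nrow(), p = X.ncol();
  if (eta.size() != n || event.size() != n || time.size() != n)
    stop("row mismatch in cox derivative inputs");

  std::vector<double> S1(p, 0.0), dS1(p, 0.0), sx(p, 0.0), mu(p);
  std::vector<double> S2, dS2;
  if (hessian) {
    S2.assign((size_t)p * p, 0.0);
    dS2.assign((size_t)p * p, 0.0);
  }
  NumericVector grad(p);
  NumericMatrix hess(hessian ? p : 1, hessian ? p : 1);
  double ll = 0.0, S0 = 0.0;

  int i = 0;
  while (i < n) {
    int j = i;
    double dS0 = 0.0, sum_lp = 0.0;
    int d = 0;
    std::fill(dS1.begin(), dS1.end(), 0.0);
    std::fill(sx.begin(), sx.end(), 0.0);
    if (hessian) std::fill(dS2.begin(), dS2.end(), 0.0);
    while (j < n && time[j] == time[i]) {
      double w = std::exp(eta[j]);
      S0 += w;
      for (int a = 0; a < p; ++a) S1[a] += w * X(j, a);
      if (hessian)
        for (int a = 0; a < p; ++a)
          for (int b = a; b < p; ++b) S2[(size_t)a * p + b] += w * X(j, a) * X(j, b);
      if (event[j] == 1) {
        ++d;
        sum_lp += eta[j];
        dS0 += w;
        for (int a = 0; a < p; ++a) {
          dS1[a] += w * X(j, a);
          sx[a] += X(j, a);
        }
        if (hessian)
          for (int a = 0; a < p; ++a)
            for (int b = a; b < p; ++b)
              dS2[(size_t)a * p + b] += w * X(j, a) * X(j, b);
      }
      ++j;
    }
    if (d > 0) {
      ll += sum_lp;
      for (int a = 0; a < p; ++a) grad[a] += sx[a];
      for (int l = 0; l < d; ++l) {
        double f = efron ? (double)l / (double)d : 0.0;
        double phi = S0 - f * dS0;
        ll -= std::log(phi);
        for (int a = 0; a < p; ++a) {
          mu[a] = (S1[a] - f * dS1[a]) / phi;
          grad[a] -= mu[a];
        }
        if (hessian) {
          for (int a = 0; a < p; ++a)
            for (int b = a; b < p; ++b) {
              double s2 = (S2[(size_t)a * p + b] - f * dS2[(size_t)a * p + b]) / phi;
              double h = -(s2 - mu[a] * mu[b]);  // d2 loglik
              hess(a, b) += h;
              if (a != b) hess(b, a) += h;
            }
        }
      }
    }
    i = j;
  }

  List out = List::create(_["loglik"] = ll, _["grad"] = grad);
  if (hessian) out["hess"] = hess;
  return out;
}
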