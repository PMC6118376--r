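#include <Rcpp.h>
using namespace Rcpp;

// Two-group logrank chi-square statistics for many candidate splits at once.
//
// `time` must be sorted ascending with `event` aligned; each column of `memb`
// is a 0/1 left-branch membership vector for one candidate split. For each
// candidate the standard observed-minus-expected sum over the risk-set
// sequence is accumulated with the hypergeometric variance, and (O-E)^2 / V
// returned (0 when V degenerates).
// [[Rcpp::export(name = ".lr_scan_cpp")]]
NumericVector lr_scan_cpp(NumericVector time, IntegerVector event,
                          IntegerMatrix memb) {
  const int n = time.size();
  const int k = memb.ncol();
  if (memb.nrow() != n || event.size() != n)
    stop("membership matrix does not match data");
  NumericVector out(k);

  for (int c = 0; c < k; ++c) {
    double natrisk = n;
    double n1 = 0.0;
    for (int i = 0; i < n; ++i) n1 += memb(i, c);
    double oe = 0.0, v = 0.0;
    int i = 0;
    while (i < n) {
      int j = i;
      double d = 0.0, d1 = 0.0, cnt = 0.0, cnt1 = 0.0;
      while (j < n && time[j] == time[i]) {
        cnt += 1.0;
        cnt1 += memb(j, c);
        if (event[j] == 1) {
          d += 1.0;
          d1 += memb(j, c);
        }
        ++j;
      }
      if (d > 0.0 && natrisk > 1.0) {
        double p1 = n1 / natrisk;
        oe += d1 - d * p1;
        v += d * p1 * (1.0 - p1) * (natrisk - d) / (natrisk - 1.0);
      }
      natrisk -= cnt;
      n1 -= cnt1;
      i = j;
    }
    out[c] = (v > 0.0) ? (oe * oe / v) : 0.0;
  }
  return out;
}
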