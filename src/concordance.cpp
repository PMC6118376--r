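#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// Fenwick / binary-indexed tree over risk ranks.
struct Fenwick {
  std::vector<double> t;
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0.0), n(n_) {}
  void add(int i, double v) {
    for (; i <= n; i += i & (-i)) t[i] += v;
  }
  double sum(int i) const {  // prefix sum over ranks 1..i
    double s = 0.0;
    for (; i > 0; i -= i & (-i)) s += t[i];
    return s;
  }
};

}  // namespace

// Harrell concordance pair counts in O(n log n).
//
// Pair conventions (Harrell):
//  * comparable: t_i < t_j with event_i = 1 (any status for j), or
//    t_i == t_j with exactly one event (the event member is 'earlier');
//  * time-tied pairs with two events are not comparable;
//  * concordant when the earlier death has the larger risk score;
//  * risk ties score 1/2.
// [[Rcpp::export(name = ".cindex_counts_cpp")]]
List cindex_counts_cpp(NumericVector time, IntegerVector event,
                       NumericVector risk) {
  const int n = time.size();
  if (event.size() != n || risk.size() != n)
    stop("time, event and risk must have equal length");

  // map risks to dense ranks 1..m
  std::vector<double> sorted(risk.begin(), risk.end());
  std::sort(sorted.begin(), sorted.end());
  sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
  const int m = (int)sorted.size();
  std::vector<int> rrank(n);
  for (int i = 0; i < n; ++i)
    rrank[i] = 1 + (int)(std::lower_bound(sorted.begin(), sorted.end(),
                                          risk[i]) - sorted.begin());

  // order by time ascending
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });

  Fenwick bit(m);
  double in_bit = 0.0;
  double conc = 0.0, disc = 0.0, tied = 0.0;

  // walk distinct times from the largest down; the BIT holds risk ranks of
  // every patient with strictly larger time
  int hi = n - 1;
  while (hi >= 0) {
    int lo = hi;
    while (lo > 0 && time[ord[lo - 1]] == time[ord[hi]]) --lo;

    // censored risks within this tied-time block, sorted, for the
    // event-vs-censored same-time comparisons
    std::vector<double> cens;
    for (int k = lo; k <= hi; ++k)
      if (event[ord[k]] == 0) cens.push_back(risk[ord[k]]);
    std::sort(cens.begin(), cens.end());

    for (int k = lo; k <= hi; ++k) {
      int i = ord[k];
      if (event[i] != 1) continue;
      // versus strictly later times
      double less = bit.sum(rrank[i] - 1);
      double eq = bit.sum(rrank[i]) - less;
      conc += less;
      tied += eq;
      disc += in_bit - less - eq;
      // versus censored at the same time
      if (!cens.empty()) {
        double cl = (double)(std::lower_bound(cens.begin(), cens.end(),
                                              risk[i]) - cens.begin());
        double cu = (double)(std::upper_bound(cens.begin(), cens.end(),
                                              risk[i]) - cens.begin());
        conc += cl;
        tied += cu - cl;
        disc += (double)cens.size() - cu;
      }
    }
    for (int k = lo; k <= hi; ++k) {
      bit.add(rrank[ord[k]], 1.0);
      in_bit += 1.0;
    }
    hi = lo - 1;
  }

  double comparable = conc + disc + tied;
  return List::create(_["concordant"] = conc, _["discordant"] = disc,
                      _["tied_risk"] = tied, _["comparable"] = comparable);
}
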