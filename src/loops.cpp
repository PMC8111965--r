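#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Sequential obstacle-limited loop placement. For each loop a uniform
// loading point is drawn; each side extends by an exponential distance
// (mean d0) but is clipped at the nearest intervening obstacle, previously
// placed anchor, or chromosome end, whichever comes first. Placed anchors
// are added to the obstacle set for subsequent loops. Zero-size loops are
// discarded and redrawn.
//
// stop reason codes: 0 = processivity, 1 = obstacle, 2 = prior_anchor,
// 3 = chrom_end
// [[Rcpp::export]]
List place_loops_cpp(double chrom_length, NumericVector obstacles, int n_loops,
                     double d0) {
  std::set<std::pair<double, int>> obs;  // position, kind (1 obstacle, 2 anchor)
  for (double o : obstacles) obs.insert({o, 1});

  NumericVector left(n_loops), right(n_loops), loading(n_loops);
  IntegerVector stop_left(n_loops), stop_right(n_loops);

  int placed = 0, attempts = 0;
  const int max_attempts = 50 * n_loops + 1000;
  while (placed < n_loops && attempts < max_attempts) {
    ++attempts;
    double lp = R::runif(0.0, chrom_length);
    double dl = R::rexp(d0);
    double dr = R::rexp(d0);

    double lf = lp - dl;
    int sl = 0;
    // nearest obstacle strictly left of the loading point
    auto it = obs.lower_bound({lp, -1});
    if (it != obs.begin()) {
      auto prev = std::prev(it);
      if (prev->first > lf) {
        lf = prev->first;
        sl = prev->second;
      }
    }
    if (lf < 0.0) { lf = 0.0; sl = 3; }

    double rt = lp + dr;
    int sr = 0;
    auto it2 = obs.upper_bound({lp, 3});
    if (it2 != obs.end() && it2->first < rt) {
      rt = it2->first;
      sr = it2->second;
    }
    if (rt > chrom_length) { rt = chrom_length; sr = 3; }

    if (rt - lf <= 0.0) continue;  // degenerate, redraw

    left[placed] = lf;
    right[placed] = rt;
    loading[placed] = lp;
    stop_left[placed] = sl;
    stop_right[placed] = sr;
    obs.insert({lf, 2});
    obs.insert({rt, 2});
    ++placed;
  }
  if (placed < n_loops) stop("could not place requested number of loops");
  return List::create(_["left"] = left, _["right"] = right,
                      _["loading_point"] = loading,
                      _["stop_left"] = stop_left,
                      _["stop_right"] = stop_right);
}
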