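#include <Rcpp.h>
using namespace Rcpp;

// Strict local maxima of a numeric series with topographic prominence.
// Plateau maxima (runs of equal values bounded by strictly lower samples on
// both sides) resolve to the plateau midpoint.  Prominence of a peak is its
// height minus the higher of the two minima found walking left/right until a
// strictly higher sample (or the series boundary) is met.
// [[Rcpp::export]]
List cpp_find_peaks(NumericVector x) {
  const int n = x.size();
  std::vector<int> idx;
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;   // plateau extent
      if (j < n - 1 && x[j + 1] < x[i]) {
        idx.push_back((i + j) / 2);                 // plateau midpoint
      }
      i = j + 1;
    } else {
      ++i;
    }
  }
  const int m = idx.size();
  NumericVector prom(m);
  for (int p = 0; p < m; ++p) {
    const int k = idx[p];
    const double h = x[k];
    double lmin = h, rmin = h;
    for (int a = k - 1; a >= 0; --a) {
      if (x[a] > h) break;
      if (x[a] < lmin) lmin = x[a];
    }
    for (int b = k + 1; b < n; ++b) {
      if (x[b] > h) break;
      if (x[b] < rmin) rmin = x[b];
    }
    prom[p] = h - std::max(lmin, rmin);
  }
  return List::create(_["index"] = wrap(idx), _["prominence"] = prom);
}
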