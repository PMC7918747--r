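#include <Rcpp.h>
using namespace Rcpp;

// Dispersion-threshold (I-DT) scan over one run of valid samples.
// Greedy: the shortest window long enough to satisfy the duration
// minimum is tested first; on success it is extended right while the
// x-range + y-range dispersion stays within the cap, then emitted.
// Returns 1-based start/end sample indices.
// [[Rcpp::export]]
List idt_run_cpp(NumericVector x, NumericVector y, int min_samples,
                 double max_dispersion) {
  int n = x.size();
  std::vector<int> starts, ends;
  int i = 0;
  while (i + min_samples - 1 < n) {
    int j = i + min_samples - 1;
    double xmin = x[i], xmax = x[i], ymin = y[i], ymax = y[i];
    for (int k = i + 1; k <= j; ++k) {
      if (x[k] < xmin) xmin = x[k];
      if (x[k] > xmax) xmax = x[k];
      if (y[k] < ymin) ymin = y[k];
      if (y[k] > ymax) ymax = y[k];
    }
    if ((xmax - xmin) + (ymax - ymin) <= max_dispersion) {
      while (j + 1 < n) {
        double nx = x[j + 1], ny = y[j + 1];
        double xmin2 = std::min(xmin, nx), xmax2 = std::max(xmax, nx);
        double ymin2 = std::min(ymin, ny), ymax2 = std::max(ymax, ny);
        if ((xmax2 - xmin2) + (ymax2 - ymin2) > max_dispersion) break;
        ++j;
        xmin = xmin2; xmax = xmax2; ymin = ymin2; ymax = ymax2;
      }
      starts.push_back(i + 1);
      ends.push_back(j + 1);
      i = j + 1;
    } else {
      ++i;
    }
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends));
}
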