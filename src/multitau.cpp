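#include <Rcpp.h>
using namespace Rcpp;

// Multi-tau accumulator. The series is coarsened in place by summing
// groups of `m` adjacent bins per stage (integer-exact in doubles for
// photon counts). For each scheduled lag k (in stage bins) it returns the
// raw accumulator G = sum n_i * n_{i+k}, the direct and delayed monitor
// sums over the same index range, and the number of usable pairs Ms.
// [[Rcpp::export]]
NumericMatrix multitau_core(NumericVector counts, IntegerVector stage,
                            IntegerVector k, int m) {
  const int n_lags = stage.size();
  std::vector<double> x(counts.begin(), counts.end());
  NumericMatrix out(n_lags, 4);
  colnames(out) = CharacterVector::create("G", "Md", "Mdel", "Ms");

  int cur_stage = 0;
  for (int i = 0; i < n_lags; ++i) {
    while (cur_stage < stage[i]) {
      // coarsen: pairwise (or m-wise) summation, truncating the remainder
      const size_t n_new = x.size() / m;
      for (size_t j = 0; j < n_new; ++j) {
        double s = 0.0;
        for (int q = 0; q < m; ++q) s += x[j * m + q];
        x[j] = s;
      }
      x.resize(n_new);
      ++cur_stage;
    }
    const int kk = k[i];
    const long ms = static_cast<long>(x.size()) - kk;
    if (ms <= 0) stop("lag exceeds coarsened series length");
    double G = 0.0, md = 0.0, mdel = 0.0;
    for (long j = 0; j < ms; ++j) {
      G += x[j] * x[j + kk];
      md += x[j];
      mdel += x[j + kk];
    }
    out(i, 0) = G;
    out(i, 1) = md;
    out(i, 2) = mdel;
    out(i, 3) = static_cast<double>(ms);
  }
  return out;
}
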