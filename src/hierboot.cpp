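#include <Rcpp.h>
using namespace Rcpp;

// Three-level hierarchical bootstrap of the difference of two group means.
//
// Each group is a List of rats; each rat a List of NumericVector cells
// (spark values). One bootstrap draw resamples rats with replacement,
// then cells within each sampled rat, then sparks within each sampled
// cell; the group mean is the mean of rat means of cell means. Uses R's
// RNG so set.seed() governs reproducibility.

static int sample_int(int n) {
  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  if (k == n) k = n - 1;
  return k;
}

static double boot_group_mean(const List &rats) {
  int R = rats.size();
  double rat_acc = 0.0;
  for (int r = 0; r < R; ++r) {
    const List cells = rats[sample_int(R)];
    int C = cells.size();
    double cell_acc = 0.0;
    for (int c = 0; c < C; ++c) {
      const NumericVector v = cells[sample_int(C)];
      int n = v.size();
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[sample_int(n)];
      cell_acc += s / n;
    }
    rat_acc += cell_acc / C;
  }
  return rat_acc / R;
}

// [[Rcpp::export]]
NumericVector hier_boot_diff_cpp(List group_a, List group_b, int B) {
  NumericVector out(B);
  GetRNGstate();
  for (int b = 0; b < B; ++b)
    out[b] = boot_group_mean(group_a) - boot_group_mean(group_b);
  PutRNGstate();
  return out;
}
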