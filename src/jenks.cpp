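#include <Rcpp.h>
using namespace Rcpp;

// Exact Fisher natural-breaks partition of sorted unique values with
// weights (tied observations collapsed by the caller). Minimizes the total
// within-class weighted sum of squared deviations over all partitions of
// the sorted sequence into k contiguous classes. O(k * m^2) dynamic
// program over m unique values.
//
// Returns a 1-based index vector of length k: the position (in the sorted
// unique values) of the last member of each class.
// [[Rcpp::export(name = ".jenks_fisher")]]
IntegerVector jenks_fisher(NumericVector u, NumericVector w, int k) {
  int m = u.size();
  if (k < 1 || k > m) stop("k out of range");
  std::vector<double> cw(m + 1, 0.0), cwx(m + 1, 0.0), cwx2(m + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwx[i + 1] = cwx[i] + w[i] * u[i];
    cwx2[i + 1] = cwx2[i] + w[i] * u[i] * u[i];
  }
  // cost of class spanning unique values i..j inclusive (0-based)
  auto cost = [&](int i, int j) {
    double W = cw[j + 1] - cw[i];
    double S = cwx[j + 1] - cwx[i];
    double S2 = cwx2[j + 1] - cwx2[i];
    double c = S2 - S * S / W;
    return c > 0 ? c : 0.0;
  };
  std::vector<std::vector<double>> D(k, std::vector<double>(m, 0.0));
  std::vector<std::vector<int>> B(k, std::vector<int>(m, 0));
  for (int j = 0; j < m; ++j) D[0][j] = cost(0, j);
  for (int c = 1; c < k; ++c) {
    for (int j = c; j < m; ++j) {
      double best = R_PosInf;
      int arg = c;
      for (int i = c; i <= j; ++i) {
        double v = D[c - 1][i - 1] + cost(i, j);
        if (v < best) { best = v; arg = i; }
      }
      D[c][j] = best;
      B[c][j] = arg;
    }
  }
  IntegerVector ends(k);
  int j = m - 1;
  for (int c = k - 1; c >= 0; --c) {
    ends[c] = j + 1;           // 1-based last index of class c
    if (c > 0) j = B[c][j] - 1;
  }
  return ends;
}
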