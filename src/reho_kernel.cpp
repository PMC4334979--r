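#include <Rcpp.h>
using namespace Rcpp;

// Kendall's W per voxel from precomputed per-voxel temporal ranks.
// ranks: nt x V (columns = in-mask voxels, midranks over time)
// tie_T: length-V tie-correction terms (sum of t^3 - t per voxel)
// nbr:   K x V matrix of 1-based column ids of each voxel's in-mask
//        neighbours (0 = neighbour absent)
// Returns W per voxel; NaN where fewer than 2 series are available.
// [[Rcpp::export]]
NumericVector reho_kernel(const NumericMatrix& ranks,
                          const NumericVector& tie_T,
                          const IntegerMatrix& nbr) {
  const int nt = ranks.nrow();
  const int V = ranks.ncol();
  const int K = nbr.nrow();
  NumericVector W(V);
  std::vector<double> R(nt);
  const double n3n = (double)nt * nt * nt - nt;
  for (int v = 0; v < V; ++v) {
    std::fill(R.begin(), R.end(), 0.0);
    int k = 0;
    double T = 0.0;
    for (int j = 0; j < K; ++j) {
      const int id = nbr(j, v);
      if (id == 0) continue;
      ++k;
      T += tie_T[id - 1];
      const double* col = &ranks(0, id - 1);
      for (int t = 0; t < nt; ++t) R[t] += col[t];
    }
    if (k < 2) { W[v] = R_NaN; continue; }
    double sum = 0.0, sumsq = 0.0;
    for (int t = 0; t < nt; ++t) { sum += R[t]; sumsq += R[t] * R[t]; }
    const double mean = sum / nt;
    const double S = sumsq - nt * mean * mean;
    const double denom = ((double)k * k * n3n - k * T) / 12.0;
    W[v] = denom > 0 ? std::min(std::max(S / denom, 0.0), 1.0) : 0.0;
  }
  return W;
}
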