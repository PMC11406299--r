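#include <Rcpp.h>
#include <vector>
#include <algorithm>

// For each query voxel, the unweighted mean of the values at the k observed
// voxels nearest in Euclidean voxel coordinates. Distance ties are broken by
// the observed voxel's linear index (ascending) so results are deterministic.
// obs_xyz / qry_xyz: integer voxel coordinates (rows = voxels, 3 columns).
// [[Rcpp::export]]
Rcpp::NumericVector knn_mean_cpp(const Rcpp::IntegerMatrix& obs_xyz,
                                 const Rcpp::NumericVector& obs_val,
                                 const Rcpp::IntegerVector& obs_lin,
                                 const Rcpp::IntegerMatrix& qry_xyz,
                                 int k) {
  const int m = obs_xyz.nrow(), q = qry_xyz.nrow();
  if (k > m) Rcpp::stop("fewer observed voxels than k");
  Rcpp::NumericVector out(q);

  std::vector<std::pair<double, int> > d(m); // (squared distance keyed with tiebreak, obs row)
  for (int iq = 0; iq < q; ++iq) {
    const double x = qry_xyz(iq, 0), y = qry_xyz(iq, 1), z = qry_xyz(iq, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = x - obs_xyz(j, 0);
      const double dy = y - obs_xyz(j, 1);
      const double dz = z - obs_xyz(j, 2);
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end(),
      [&](const std::pair<double, int>& a, const std::pair<double, int>& b) {
        if (a.first != b.first) return a.first < b.first;
        return obs_lin[a.second] < obs_lin[b.second];
      });
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += obs_val[d[j].second];
    out[iq] = s / k;
  }
  return out;
}
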