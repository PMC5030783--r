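#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact 1-D k-means on a weighted multiset of values (minimum within-cluster
// sum of squares). Because the optimal 1-D partition is contiguous in sorted
// order, a dynamic program over the run-length-encoded histogram solves the
// objective exactly, with no seed sensitivity. O(k * d^2) over d distinct
// values, which is small for integer-quantized microscope intensities.
//
// values: strictly increasing distinct values; counts: positive weights.
// Returns 1-based index of the last distinct value in each cluster, cluster
// means, cluster weights and the total within-cluster SSE.
// [[Rcpp::export(name = ".kmeans1d_dp")]]
List kmeans1d_dp(NumericVector values, NumericVector counts, int k) {
  const int d = values.size();
  if (d == 0) stop("no values to cluster");
  if (counts.size() != d) stop("values/counts length mismatch");
  if (k < 1) stop("k must be >= 1");
  if (k > d) k = d;

  // prefix sums of weight, weighted value, weighted square
  std::vector<long double> W(d + 1, 0.0L), S(d + 1, 0.0L), Q(d + 1, 0.0L);
  for (int i = 0; i < d; ++i) {
    W[i + 1] = W[i] + (long double)counts[i];
    S[i + 1] = S[i] + (long double)counts[i] * values[i];
    Q[i + 1] = Q[i] + (long double)counts[i] * values[i] * values[i];
  }
  // SSE of the contiguous block (i, j] (0-based half-open over distinct idx)
  auto sse = [&](int i, int j) -> long double {
    long double w = W[j] - W[i];
    if (w <= 0) return 0.0L;
    long double s = S[j] - S[i];
    long double q = Q[j] - Q[i];
    long double v = q - s * s / w;
    return v > 0 ? v : 0.0L;
  };

  const long double INF = 1e300L;
  // D[c][j]: min SSE of first j distinct values in c clusters
  std::vector<std::vector<long double> > D(k + 1,
      std::vector<long double>(d + 1, INF));
  std::vector<std::vector<int> > B(k + 1, std::vector<int>(d + 1, 0));
  D[0][0] = 0.0L;
  for (int c = 1; c <= k; ++c) {
    // each cluster non-empty: j >= c, split point i >= c-1
    for (int j = c; j <= d; ++j) {
      for (int i = c - 1; i < j; ++i) {
        if (D[c - 1][i] >= INF) continue;
        long double cand = D[c - 1][i] + sse(i, j);
        if (cand < D[c][j]) { D[c][j] = cand; B[c][j] = i; }
      }
    }
  }

  IntegerVector ends(k);
  int j = d;
  for (int c = k; c >= 1; --c) { ends[c - 1] = j; j = B[c][j]; }
  NumericVector means(k), weights(k);
  int lo = 0;
  for (int c = 0; c < k; ++c) {
    int hi = ends[c];
    long double w = W[hi] - W[lo];
    means[c] = (double)((S[hi] - S[lo]) / w);
    weights[c] = (double)w;
    lo = hi;
  }
  return List::create(_["ends"] = ends, _["means"] = means,
                      _["sizes"] = weights, _["sse"] = (double)D[k][d],
                      _["k"] = k);
}

// 26-connectivity connected-component labelling of a 3-D logical mask laid
// out as an R array (dim = c(nz, ny, nx), column-major). Iterative BFS;
// labels are 1..n_components in first-voxel order, background is 0.
// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t u = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[u] && lab[u] == 0) {
              lab[u] = next;
              queue.push_back(u);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
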