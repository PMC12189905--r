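#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Column-wise midranks plus the Kendall tie-correction term
// sum_groups (g^3 - g) for each column.
// [[Rcpp::export]]
List rank_cols_ties(NumericMatrix x) {
  int n = x.nrow(), V = x.ncol();
  NumericMatrix r(n, V);
  NumericVector tie(V);
  std::vector<int> idx(n);
  for (int v = 0; v < V; ++v) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    NumericMatrix::Column col = x(_, v);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    double tt = 0.0;
    int i = 0;
    while (i < n) {
      int j = i;
      while (j + 1 < n && col[idx[j + 1]] == col[idx[i]]) ++j;
      double mr = (i + j) / 2.0 + 1.0;
      double g = j - i + 1;
      if (g > 1) tt += g * g * g - g;
      for (int k = i; k <= j; ++k) r(idx[k], v) = mr;
      i = j + 1;
    }
    tie[v] = tt;
  }
  return List::create(_["ranks"] = r, _["ties"] = tie);
}

// Kendall's W for each target voxel over the ranks of its neighborhood
// members. Neighbor column indices (0-based, into `ranks`) for target m are
// nb_idx[nb_ptr[m] .. nb_ptr[m+1]-1]. Returns W (NA when undefined) and the
// neighbor count actually used.
// [[Rcpp::export]]
List kcc_neighbors(NumericMatrix ranks, NumericVector ties,
                   IntegerVector nb_idx, IntegerVector nb_ptr) {
  int n = ranks.nrow();
  int M = nb_ptr.size() - 1;
  NumericVector W(M);
  IntegerVector K(M);
  std::vector<double> rsum(n);
  for (int m = 0; m < M; ++m) {
    int a = nb_ptr[m], b = nb_ptr[m + 1];
    int k = b - a;
    K[m] = k;
    if (k < 2) { W[m] = NA_REAL; continue; }
    std::fill(rsum.begin(), rsum.end(), 0.0);
    double tsum = 0.0;
    for (int j = a; j < b; ++j) {
      int c = nb_idx[j];
      tsum += ties[c];
      for (int t = 0; t < n; ++t) rsum[t] += ranks(t, c);
    }
    double rbar = k * (n + 1) / 2.0, S = 0.0;
    for (int t = 0; t < n; ++t) {
      double d = rsum[t] - rbar;
      S += d * d;
    }
    double kk = k;
    double denom = kk * kk * ((double)n * n * n - n) - kk * tsum;
    W[m] = (denom > 0) ? 12.0 * S / denom : NA_REAL;
  }
  return List::create(_["W"] = W, _["K"] = K);
}

// Connected-component labelling of a 3D logical array under 6/18/26
// connectivity. Returns an integer array of labels (0 = background).
// [[Rcpp::export]]
IntegerVector label_clusters_cpp(LogicalVector mask, IntegerVector dim,
                                 int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int V = nx * ny * nz;
  IntegerVector lab(V);
  // neighbor offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  int nOff = dx.size();
  int cur = 0;
  std::vector<int> stack;
  for (int v = 0; v < V; ++v) {
    if (!mask[v] || lab[v] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(v);
    lab[v] = cur;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      for (int o = 0; o < nOff; ++o) {
        int xx = x + dx[o], yy = y + dy[o], zz = z + dz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
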