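// Image-processing primitives used by nucleus detection and WSI tissue
// masking: separable Gaussian blur, median filter, connected components,
// exact Euclidean distance transform, marker-based watershed, max filter.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <algorithm>

using namespace Rcpp;
using arma::mat;

// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; j++)  // vertical pass (reflect edges)
    for (int i = 0; i < H; i++) {
      double acc = 0;
      for (int d = -r; d <= r; d++) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= H) ii = 2 * H - ii - 1;
        acc += k[d + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; j++)  // horizontal pass
    for (int i = 0; i < H; i++) {
      double acc = 0;
      for (int d = -r; d <= r; d++) {
        int jj = j + d;
        if (jj < 0) jj = -jj - 1;
        if (jj >= W) jj = 2 * W - jj - 1;
        acc += k[d + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  std::vector<double> win;
  win.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      win.clear();
      for (int dj = -radius; dj <= radius; dj++)
        for (int di = -radius; di <= radius; di++) {
          const int ii = std::min(std::max(i + di, 0), H - 1);
          const int jj = std::min(std::max(j + dj, 0), W - 1);
          win.push_back(img(ii, jj));
        }
      const size_t m = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + m, win.end());
      out(i, j) = win[m];
    }
  return out;
}

// 4- or 8-connected component labelling of a binary matrix (labels 1..n, 0 bg)
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix bin, int connectivity = 4) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int d4[4][2] = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
  const int d8[8][2] = {{-1, 0}, {1, 0}, {0, -1}, {0, 1},
                        {-1, -1}, {-1, 1}, {1, -1}, {1, 1}};
  const int nd = connectivity == 8 ? 8 : 4;
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      if (!bin(i, j) || lab(i, j) != 0) continue;
      next++;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int d = 0; d < nd; d++) {
          const int ni = ci + (connectivity == 8 ? d8[d][0] : d4[d][0]);
          const int nj = cj + (connectivity == 8 ? d8[d][1] : d4[d][1]);
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (bin(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back({ni, nj});
          }
        }
      }
    }
  return lab;
}

// Felzenszwalb-Huttenlocher 1-d squared distance transform
static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  const int n = f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// exact Euclidean distance (to the nearest background pixel) inside foreground
// [[Rcpp::export]]
NumericMatrix distance_transform_cpp(LogicalMatrix bin) {
  const int H = bin.nrow(), W = bin.ncol();
  mat f(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) f(i, j) = bin(i, j) ? 1e30 : 0.0;
  std::vector<double> col(H), dcol(H), row(W), drow(W);
  for (int j = 0; j < W; j++) {
    for (int i = 0; i < H; i++) col[i] = f(i, j);
    dt1d(col, dcol);
    for (int i = 0; i < H; i++) f(i, j) = dcol[i];
  }
  for (int i = 0; i < H; i++) {
    for (int j = 0; j < W; j++) row[j] = f(i, j);
    dt1d(row, drow);
    for (int j = 0; j < W; j++) f(i, j) = drow[j];
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) out(i, j) = std::sqrt(f(i, j));
  return out;
}

// sliding-window maximum (Chebyshev radius), used for peak finding
// [[Rcpp::export]]
NumericMatrix max_filter_cpp(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double m = -1e300;
      for (int d = -radius; d <= radius; d++) {
        const int ii = std::min(std::max(i + d, 0), H - 1);
        m = std::max(m, img(ii, j));
      }
      tmp(i, j) = m;
    }
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double m = -1e300;
      for (int d = -radius; d <= radius; d++) {
        const int jj = std::min(std::max(j + d, 0), W - 1);
        m = std::max(m, tmp(i, jj));
      }
      out(i, j) = m;
    }
  return out;
}

// marker-based watershed by priority flooding on -elevation (higher elevation
// flooded first); regions grow from markers within the foreground mask
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix elevation, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int H = elevation.nrow(), W = elevation.ncol();
  IntegerMatrix lab = clone(markers);
  struct Node {
    double prio;
    long order;
    int i, j;
  };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on elevation
      return a.order > b.order;                      // FIFO tie-break
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long order = 0;
  const int d4[4][2] = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++)
      if (lab(i, j) > 0 && mask(i, j))
        pq.push({elevation(i, j), order++, i, j});
  while (!pq.empty()) {
    Node n = pq.top();
    pq.pop();
    for (int d = 0; d < 4; d++) {
      const int ni = n.i + d4[d][0], nj = n.j + d4[d][1];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = lab(n.i, n.j);
      pq.push({elevation(ni, nj), order++, ni, nj});
    }
  }
  return lab;
}
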