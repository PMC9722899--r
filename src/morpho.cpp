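// Grayscale morphological reconstruction and regional maxima, used for
// prominence-based (h-maxima) peak detection on score maps.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Reconstruction by dilation of `marker` under `mask` (8-connectivity),
// Vincent's hybrid raster/anti-raster algorithm with a FIFO cleanup queue.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  const int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("marker/mask shape mismatch");
  NumericMatrix J(clone(marker));
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (J(i, j) > mask(i, j)) J(i, j) = mask(i, j);

  auto raster = [&](bool forward) {
    if (forward) {
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double m = J(i, j);
          if (i > 0) m = std::max(m, J(i - 1, j));
          if (j > 0) m = std::max(m, J(i, j - 1));
          if (i > 0 && j > 0) m = std::max(m, J(i - 1, j - 1));
          if (i < H - 1 && j > 0) m = std::max(m, J(i + 1, j - 1));
          J(i, j) = std::min(m, mask(i, j));
        }
    } else {
      for (int j = W - 1; j >= 0; --j)
        for (int i = H - 1; i >= 0; --i) {
          double m = J(i, j);
          if (i < H - 1) m = std::max(m, J(i + 1, j));
          if (j < W - 1) m = std::max(m, J(i, j + 1));
          if (i < H - 1 && j < W - 1) m = std::max(m, J(i + 1, j + 1));
          if (i > 0 && j < W - 1) m = std::max(m, J(i - 1, j + 1));
          J(i, j) = std::min(m, mask(i, j));
        }
    }
  };
  raster(true);
  raster(false);

  std::queue<std::pair<int, int>> fifo;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
          if (J(ni, nj) < J(i, j) && J(ni, nj) < mask(ni, nj)) {
            fifo.push({i, j});
            di = 2; dj = 2;  // break both loops
          }
        }
  while (!fifo.empty()) {
    auto [i, j] = fifo.front(); fifo.pop();
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ni = i + di, nj = j + dj;
        if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
        if (J(ni, nj) < J(i, j) && mask(ni, nj) != J(ni, nj)) {
          J(ni, nj) = std::min(J(i, j), mask(ni, nj));
          fifo.push({ni, nj});
        }
      }
  }
  return J;
}

// Regional maxima (8-connectivity): labels > 0 for plateaus with no strictly
// greater neighbour, 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);           // 0 = unvisited/background
  int next_label = 0;
  std::vector<std::pair<int, int>> plateau;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (lab(i0, j0) != 0) continue;
      // flood the equal-valued plateau containing (i0, j0)
      double v = x(i0, j0);
      bool is_max = true;
      plateau.clear();
      std::queue<std::pair<int, int>> q;
      q.push({i0, j0});
      lab(i0, j0) = -1;              // mark visiting
      while (!q.empty()) {
        auto [i, j] = q.front(); q.pop();
        plateau.push_back({i, j});
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = i + di, nj = j + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            double nv = x(ni, nj);
            if (nv > v) is_max = false;
            else if (nv == v && lab(ni, nj) == 0) {
              lab(ni, nj) = -1;
              q.push({ni, nj});
            }
          }
      }
      int assign = is_max ? ++next_label : -2;
      for (auto& p : plateau) lab(p.first, p.second) = assign;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) < 0) lab(i, j) = 0;
  return lab;
}
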