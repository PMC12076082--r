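#include <Rcpp.h>
#include <vector>
#include <set>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double dx, double L) {
  return dx - L * std::round(dx / L);
}

// Intermolecular bead pairs closer than `cutoff` (strict <) under the
// minimum-image convention. Cell-list search; falls back to an all-pairs
// scan when the box is too small for a 3x3x3 cell neighbourhood.
// Returns a 2-column matrix of 1-based bead indices, each unordered pair
// exactly once (i < j), ordered lexicographically.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix xyz, IntegerVector mol,
                                NumericVector box, double cutoff) {
  const int n = xyz.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<std::pair<int, int> > pairs;

  // wrap coordinates into [0, L)
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) {
    X[i] = xyz(i, 0) - box[0] * std::floor(xyz(i, 0) / box[0]);
    Y[i] = xyz(i, 1) - box[1] * std::floor(xyz(i, 1) / box[1]);
    Z[i] = xyz(i, 2) - box[2] * std::floor(xyz(i, 2) / box[2]);
  }

  int nc[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = std::max(1, (int)std::floor(box[k] / cutoff));
  }
  bool use_cells = nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3 && n > 64;

  if (!use_cells) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (mol[i] == mol[j]) continue;
        double dx = min_image(X[i] - X[j], box[0]);
        double dy = min_image(Y[i] - Y[j], box[1]);
        double dz = min_image(Z[i] - Z[j], box[2]);
        if (dx * dx + dy * dy + dz * dz < c2)
          pairs.push_back(std::make_pair(i, j));
      }
    }
  } else {
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1), cell_of(n);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(nc[0] - 1, (int)(X[i] / box[0] * nc[0]));
      int cy = std::min(nc[1] - 1, (int)(Y[i] / box[1] * nc[1]));
      int cz = std::min(nc[2] - 1, (int)(Z[i] / box[2] * nc[2]));
      int c = (cz * nc[1] + cy) * nc[0] + cx;
      cell_of[i] = c;
      nxt[i] = head[c];
      head[c] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c = (cz * nc[1] + cy) * nc[0] + cx;
          if (head[c] < 0) continue;
          // distinct neighbour cells (periodic); keep self and higher ids
          std::set<int> nb;
          for (int oz = -1; oz <= 1; ++oz)
            for (int oy = -1; oy <= 1; ++oy)
              for (int ox = -1; ox <= 1; ++ox) {
                int ax = (cx + ox + nc[0]) % nc[0];
                int ay = (cy + oy + nc[1]) % nc[1];
                int az = (cz + oz + nc[2]) % nc[2];
                nb.insert((az * nc[1] + ay) * nc[0] + ax);
              }
          for (std::set<int>::iterator it = nb.begin(); it != nb.end();
               ++it) {
            int cn = *it;
            if (cn < c) continue;
            for (int i = head[c]; i >= 0; i = nxt[i]) {
              int jstart = (cn == c) ? nxt[i] : head[cn];
              for (int j = jstart; j >= 0; j = nxt[j]) {
                if (mol[i] == mol[j]) continue;
                double dx = min_image(X[i] - X[j], box[0]);
                double dy = min_image(Y[i] - Y[j], box[1]);
                double dz = min_image(Z[i] - Z[j], box[2]);
                if (dx * dx + dy * dy + dz * dz < c2) {
                  int a = i < j ? i : j, b = i < j ? j : i;
                  pairs.push_back(std::make_pair(a, b));
                }
              }
            }
          }
        }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first + 1;
    out(k, 1) = pairs[k].second + 1;
  }
  return out;
}

// Connected-component labelling of a logical mask (4- or 8-connectivity).
// Returns an integer matrix of labels, 0 = background, components numbered
// in raster-scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), ncol = mask.ncol();
  IntegerMatrix lab(nr, ncol);
  int next = 0;
  const int dx4[] = {-1, 1, 0, 0};
  const int dy4[] = {0, 0, -1, 1};
  const int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dx = connectivity == 8 ? dx8 : dx4;
  const int *dy = connectivity == 8 ? dy8 : dy4;
  const int nd = connectivity == 8 ? 8 : 4;
  for (int j = 0; j < ncol; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(i, j));
      lab(i, j) = next;
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nd; ++k) {
          int ii = p.first + dx[k], jj = p.second + dy[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= ncol) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}
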