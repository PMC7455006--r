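#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double torus_dist2(double x1, double y1, double x2, double y2,
                                 double sx, double sy) {
  double dx = std::fabs(x1 - x2); if (dx > sx - dx) dx = sx - dx;
  double dy = std::fabs(y1 - y2); if (dy > sy - dy) dy = sy - dy;
  return dx * dx + dy * dy;
}

// Uniform grid over the torus with cell size >= radius: a query inspects
// the 3x3 block of cells around the query point. Falls back to an
// all-pairs scan when the area is too small to hold a 3x3 block of
// distinct cells.
// [[Rcpp::export]]
List grid_neighbors_cpp(NumericVector x, NumericVector y, double sizeX,
                        double sizeY, double radius) {
  const int n = x.size();
  List out(n);
  const int nx = std::max(1, (int)std::floor(sizeX / radius));
  const int ny = std::max(1, (int)std::floor(sizeY / radius));
  const double r2 = radius * radius;
  if (nx < 3 || ny < 3) {
    for (int i = 0; i < n; ++i) {
      std::vector<int> nb;
      for (int j = 0; j < n; ++j)
        if (j != i &&
            torus_dist2(x[i], y[i], x[j], y[j], sizeX, sizeY) < r2)
          nb.push_back(j + 1);
      out[i] = IntegerVector(nb.begin(), nb.end());
    }
    return out;
  }
  const double cx = sizeX / nx, cy = sizeY / ny;
  std::vector<std::vector<int> > cells((size_t)nx * ny);
  std::vector<int> ci(n), cj(n);
  for (int i = 0; i < n; ++i) {
    int a = (int)(x[i] / cx); if (a >= nx) a = nx - 1;
    int b = (int)(y[i] / cy); if (b >= ny) b = ny - 1;
    ci[i] = a; cj[i] = b;
    cells[(size_t)a * ny + b].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int da = -1; da <= 1; ++da) {
      int a = (ci[i] + da + nx) % nx;
      for (int db = -1; db <= 1; ++db) {
        int b = (cj[i] + db + ny) % ny;
        const std::vector<int>& bucket = cells[(size_t)a * ny + b];
        for (size_t t = 0; t < bucket.size(); ++t) {
          int j = bucket[t];
          if (j != i &&
              torus_dist2(x[i], y[i], x[j], y[j], sizeX, sizeY) < r2)
            nb.push_back(j + 1);
        }
      }
    }
    std::sort(nb.begin(), nb.end());
    out[i] = IntegerVector(nb.begin(), nb.end());
  }
  return out;
}
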