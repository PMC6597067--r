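#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list (grid bucket) neighbour search.  Points are bucketed into square
// cells of side >= cutoff so that all pairs within the cutoff live in
// adjacent buckets; axon heads may fall outside the unit square, so the grid
// is anchored at the joint bounding box of both point sets.

namespace {

struct CellGrid {
  double x0, y0, h;
  int nx, ny;
  std::vector<std::vector<int> > cells;

  CellGrid(const NumericVector& x, const NumericVector& y,
           double xmin, double ymin, double xmax, double ymax, double cutoff) {
    x0 = xmin; y0 = ymin;
    h = cutoff > 0 ? cutoff : 1.0;
    nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
    cells.resize((size_t)nx * ny);
    for (int i = 0; i < x.size(); ++i)
      cells[index_of(x[i], y[i])].push_back(i);
  }
  int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  size_t index_of(double x, double y) const {
    int cx = clampi((int)std::floor((x - x0) / h), 0, nx - 1);
    int cy = clampi((int)std::floor((y - y0) / h), 0, ny - 1);
    return (size_t)cy * nx + cx;
  }
};

void bbox(const NumericVector& x, const NumericVector& y,
          double& xmin, double& ymin, double& xmax, double& ymax) {
  for (int i = 0; i < x.size(); ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
}

} // namespace

// Pairs (i, j), i < j, with Euclidean distance <= cutoff.  1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_close_pairs(NumericVector x, NumericVector y, double cutoff) {
  int n = x.size();
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  if (n == 0) return IntegerMatrix(0, 2);
  bbox(x, y, xmin, ymin, xmax, ymax);
  CellGrid g(x, y, xmin, ymin, xmax, ymax, cutoff);
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int cy = 0; cy < g.ny; ++cy) {
    for (int cx = 0; cx < g.nx; ++cx) {
      const std::vector<int>& a = g.cells[(size_t)cy * g.nx + cx];
      if (a.empty()) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          int ux = cx + dx, uy = cy + dy;
          if (ux < 0 || uy < 0 || ux >= g.nx || uy >= g.ny) continue;
          const std::vector<int>& b = g.cells[(size_t)uy * g.nx + ux];
          for (size_t s = 0; s < a.size(); ++s) {
            for (size_t t = 0; t < b.size(); ++t) {
              int i = a[s], j = b[t];
              if (i >= j) continue;
              double ddx = x[i] - x[j], ddy = y[i] - y[j];
              if (ddx * ddx + ddy * ddy <= c2) {
                ii.push_back(i + 1);
                jj.push_back(j + 1);
              }
            }
          }
        }
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

// Cross-set pairs (i in A, j in B) with distance <= cutoff.  1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_cross_pairs(NumericVector ax, NumericVector ay,
                              NumericVector bx, NumericVector by,
                              double cutoff) {
  if (ax.size() == 0 || bx.size() == 0) return IntegerMatrix(0, 2);
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  bbox(ax, ay, xmin, ymin, xmax, ymax);
  bbox(bx, by, xmin, ymin, xmax, ymax);
  CellGrid g(bx, by, xmin, ymin, xmax, ymax, cutoff);
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < ax.size(); ++i) {
    int cx = g.clampi((int)std::floor((ax[i] - g.x0) / g.h), 0, g.nx - 1);
    int cy = g.clampi((int)std::floor((ay[i] - g.y0) / g.h), 0, g.ny - 1);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int ux = cx + dx, uy = cy + dy;
        if (ux < 0 || uy < 0 || ux >= g.nx || uy >= g.ny) continue;
        const std::vector<int>& b = g.cells[(size_t)uy * g.nx + ux];
        for (size_t t = 0; t < b.size(); ++t) {
          int j = b[t];
          double ddx = ax[i] - bx[j], ddy = ay[i] - by[j];
          if (ddx * ddx + ddy * ddy <= c2) {
            ii.push_back(i + 1);
            jj.push_back(j + 1);
          }
        }
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
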