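#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Uniform-grid spatial index over 2D points. Cell size is chosen by the
// caller; neighborhoods are exact (the grid only prunes candidates, every
// candidate is distance-checked), so results are identical to an exhaustive
// scan.
namespace {

struct Grid {
  double cell;
  double x0, y0;
  std::unordered_map<long long, std::vector<int> > cells;

  static long long key(long long ix, long long iy) {
    // interleave-free packing; coordinates fit easily in 2^31 cells
    return (ix << 32) ^ (iy & 0xffffffffLL);
  }

  Grid(const NumericVector& x, const NumericVector& y, double cell_size)
      : cell(cell_size) {
    x0 = R_PosInf; y0 = R_PosInf;
    int n = x.size();
    for (int i = 0; i < n; ++i) {
      if (x[i] < x0) x0 = x[i];
      if (y[i] < y0) y0 = y[i];
    }
    if (n == 0) { x0 = 0.0; y0 = 0.0; }
    cells.reserve(n * 2 + 1);
    for (int i = 0; i < n; ++i) {
      long long ix = (long long) std::floor((x[i] - x0) / cell);
      long long iy = (long long) std::floor((y[i] - y0) / cell);
      cells[key(ix, iy)].push_back(i);
    }
  }

  void cell_of(double px, double py, long long& ix, long long& iy) const {
    ix = (long long) std::floor((px - x0) / cell);
    iy = (long long) std::floor((py - y0) / cell);
  }
};

inline double sqdist(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return dx * dx + dy * dy;
}

// All point indices within `radius` (closed ball) of point i, self included.
void neighbors_within(const Grid& g, const NumericVector& x,
                      const NumericVector& y, int i, double radius,
                      std::vector<int>& out) {
  out.clear();
  double r2 = radius * radius;
  long long cx, cy;
  g.cell_of(x[i], y[i], cx, cy);
  // cell size == radius, so a 3x3 block of cells covers the ball
  for (long long ix = cx - 1; ix <= cx + 1; ++ix) {
    for (long long iy = cy - 1; iy <= cy + 1; ++iy) {
      auto it = g.cells.find(Grid::key(ix, iy));
      if (it == g.cells.end()) continue;
      for (int j : it->second) {
        if (sqdist(x[i], y[i], x[j], y[j]) <= r2) out.push_back(j);
      }
    }
  }
}

}  // namespace

// DBSCAN on a 2D point set. Core point: >= min_count points (self included)
// within `radius` (closed ball). Clusters are connected components of core
// points under radius adjacency. Border points (non-core within radius of a
// core point) are assigned to the cluster of the nearest core point, ties
// broken by lowest cluster id. Cluster ids are relabeled so that id order
// follows the lowest member row index; noise is 0. Core/noise status and the
// partition are independent of input row order.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double radius,
                         int min_count) {
  int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  Grid g(x, y, radius);
  std::vector<std::vector<int> > nbr(n);
  std::vector<bool> core(n, false);
  for (int i = 0; i < n; ++i) {
    neighbors_within(g, x, y, i, radius, nbr[i]);
    core[i] = (int) nbr[i].size() >= min_count;
  }

  // components of core points, seeded in row order -> provisional ids
  std::vector<int> comp(n, 0);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || comp[i] != 0) continue;
    ++next_id;
    std::queue<int> q;
    comp[i] = next_id;
    q.push(i);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nbr[u]) {
        if (core[v] && comp[v] == 0) {
          comp[v] = next_id;
          q.push(v);
        }
      }
    }
  }

  // border points: nearest core neighbor within radius, ties -> lowest id
  for (int i = 0; i < n; ++i) {
    if (core[i]) { labels[i] = comp[i]; continue; }
    double best = std::numeric_limits<double>::infinity();
    int best_id = 0;
    for (int v : nbr[i]) {
      if (!core[v]) continue;
      double d2 = sqdist(x[i], y[i], x[v], y[v]);
      if (d2 < best || (d2 == best && comp[v] < best_id)) {
        best = d2;
        best_id = comp[v];
      }
    }
    labels[i] = best_id;  // 0 if no core neighbor -> noise
  }

  // relabel so cluster ids are ordered by lowest member row index
  std::vector<int> order;  // provisional id -> new id
  order.assign(next_id + 1, 0);
  int assigned = 0;
  for (int i = 0; i < n && assigned < next_id; ++i) {
    int c = labels[i];
    if (c > 0 && order[c] == 0) order[c] = ++assigned;
  }
  for (int i = 0; i < n; ++i) {
    if (labels[i] > 0) labels[i] = order[labels[i]];
  }
  return labels;
}

// Nearest-neighbor distance from each query point to the reference set,
// exact, via expanding ring search over a uniform grid. If exclude_self is
// true the reference with the same index as the query is skipped (use only
// when query and reference are the same table in the same order).
// [[Rcpp::export]]
NumericVector cpp_nnd(NumericVector qx, NumericVector qy, NumericVector rx,
                      NumericVector ry, bool exclude_self) {
  int nq = qx.size(), nr = rx.size();
  NumericVector out(nq, NA_REAL);
  if (nq == 0 || nr == 0 || (exclude_self && nr < 2)) return out;

  // cell size ~ expected NN spacing keeps candidate lists short
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < nr; ++i) {
    xmin = std::min(xmin, rx[i]); xmax = std::max(xmax, rx[i]);
    ymin = std::min(ymin, ry[i]); ymax = std::max(ymax, ry[i]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = span > 0 ? std::max(span / std::sqrt((double) nr), span * 1e-9)
                         : 1.0;
  Grid g(rx, ry, cell);

  for (int i = 0; i < nq; ++i) {
    long long cx, cy;
    g.cell_of(qx[i], qy[i], cx, cy);
    double best = std::numeric_limits<double>::infinity();
    for (long long ring = 0;; ++ring) {
      // points in cells of this ring are at squared distance
      // >= ((ring-1)*cell)^2 from the query; once that exceeds best, stop
      if (ring > 1) {
        double lo = (ring - 1) * cell;
        if (lo * lo > best) break;
      }
      for (long long ix = cx - ring; ix <= cx + ring; ++ix) {
        for (long long iy = cy - ring; iy <= cy + ring; ++iy) {
          if (ring > 0 && std::llabs(ix - cx) != ring &&
              std::llabs(iy - cy) != ring)
            continue;  // interior already visited
          auto it = g.cells.find(Grid::key(ix, iy));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (exclude_self && j == i) continue;
            double d2 = sqdist(qx[i], qy[i], rx[j], ry[j]);
            if (d2 < best) best = d2;
          }
        }
      }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Neighbor counts within a closed ball of `radius` (self included); used by
// tests and by density diagnostics.
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericVector x, NumericVector y,
                               double radius) {
  int n = x.size();
  IntegerVector out(n, 0);
  if (n == 0) return out;
  Grid g(x, y, radius);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    neighbors_within(g, x, y, i, radius, nb);
    out[i] = (int) nb.size();
  }
  return out;
}
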