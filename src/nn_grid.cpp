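#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Uniform-grid cell list for nearest-neighbor queries between 3D point sets.
// Reference points are binned into cubic cells; each query expands rings of
// cells outward until the best distance cannot improve. Suited to the dense,
// surface-like clouds used here (boundary clouds, dendrite node sets).

struct CellGrid {
  double ox, oy, oz, h;
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  int idx(int i, int j, int k) const { return (k * ny + j) * nx + i; }
};

static CellGrid build_grid(const NumericMatrix& ref, double h) {
  CellGrid g;
  g.h = h;
  double inf = std::numeric_limits<double>::infinity();
  double x0 = inf, y0 = inf, z0 = inf, x1 = -inf, y1 = -inf, z1 = -inf;
  int n = ref.nrow();
  for (int i = 0; i < n; ++i) {
    x0 = std::min(x0, ref(i,0)); x1 = std::max(x1, ref(i,0));
    y0 = std::min(y0, ref(i,1)); y1 = std::max(y1, ref(i,1));
    z0 = std::min(z0, ref(i,2)); z1 = std::max(z1, ref(i,2));
  }
  g.ox = x0; g.oy = y0; g.oz = z0;
  g.nx = std::max(1, (int)std::floor((x1 - x0) / h) + 1);
  g.ny = std::max(1, (int)std::floor((y1 - y0) / h) + 1);
  g.nz = std::max(1, (int)std::floor((z1 - z0) / h) + 1);
  g.cells.resize((size_t)g.nx * g.ny * g.nz);
  for (int i = 0; i < n; ++i) {
    int ci = std::min(g.nx - 1, (int)((ref(i,0) - g.ox) / h));
    int cj = std::min(g.ny - 1, (int)((ref(i,1) - g.oy) / h));
    int ck = std::min(g.nz - 1, (int)((ref(i,2) - g.oz) / h));
    g.cells[g.idx(ci, cj, ck)].push_back(i);
  }
  return g;
}

// [[Rcpp::export(name = ".nn_grid")]]
List nn_grid(NumericMatrix query, NumericMatrix ref, double cell_size) {
  if (ref.nrow() == 0) stop("reference point set is empty");
  CellGrid g = build_grid(ref, cell_size);
  int nq = query.nrow();
  IntegerVector out_idx(nq);
  NumericVector out_d(nq);
  int max_ring = g.nx + g.ny + g.nz + 3;
  for (int q = 0; q < nq; ++q) {
    double px = query(q,0), py = query(q,1), pz = query(q,2);
    int ci = std::min(g.nx - 1, std::max(0, (int)((px - g.ox) / g.h)));
    int cj = std::min(g.ny - 1, std::max(0, (int)((py - g.oy) / g.h)));
    int ck = std::min(g.nz - 1, std::max(0, (int)((pz - g.oz) / g.h)));
    double best = std::numeric_limits<double>::infinity();
    int best_i = -1;
    for (int ring = 0; ring < max_ring; ++ring) {
      // once a hit exists, stop after the first ring that cannot improve it
      if (best_i >= 0 && (double)(ring - 1) * g.h > std::sqrt(best)) break;
      bool any_cell = false;
      int i0 = ci - ring, i1 = ci + ring;
      int j0 = cj - ring, j1 = cj + ring;
      int k0 = ck - ring, k1 = ck + ring;
      for (int k = k0; k <= k1; ++k) {
        if (k < 0 || k >= g.nz) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= g.ny) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= g.nx) continue;
            // shell only: skip interior cells already visited
            if (ring > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1) continue;
            any_cell = true;
            const std::vector<int>& cell = g.cells[g.idx(i, j, k)];
            for (size_t m = 0; m < cell.size(); ++m) {
              int r = cell[m];
              double dx = ref(r,0) - px, dy = ref(r,1) - py, dz = ref(r,2) - pz;
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 < best) { best = d2; best_i = r; }
            }
          }
        }
      }
      if (!any_cell && best_i >= 0) break;
    }
    out_idx[q] = best_i + 1;  // 1-based for R
    out_d[q] = std::sqrt(best);
  }
  return List::create(_["index"] = out_idx, _["distance"] = out_d);
}

// [[Rcpp::export(name = ".min_crossdist")]]
NumericVector min_crossdist(NumericMatrix a, NumericMatrix b) {
  // For each row of a, the minimum Euclidean distance to any row of b
  // (brute force; used for small sets such as per-cube proximity tests).
  int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nb; ++j) {
      double dx = a(i,0)-b(j,0), dy = a(i,1)-b(j,1), dz = a(i,2)-b(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
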