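#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Seeded 26-connected component of a 3-D logical array.
// mask: logical vector in column-major (x fastest) order; dims length 3;
// seed: 0-based linear index into mask. Returns logical array same shape.
// [[Rcpp::export(name = ".cc3d_seed")]]
LogicalVector cc3d_seed(LogicalVector mask, IntegerVector dims, int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (seed < 0 || seed >= n) stop("seed index out of range");
  LogicalVector out(n);
  if (!mask[seed]) return out;
  std::vector<char> visited(n, 0);
  std::queue<R_xlen_t> q;
  q.push(seed);
  visited[seed] = 1;
  out[seed] = TRUE;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int z = (int)(v / sxy);
    R_xlen_t r = v - (R_xlen_t)z * sxy;
    int y = (int)(r / nx);
    int x = (int)(r - (R_xlen_t)y * nx);
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          R_xlen_t w = (R_xlen_t)zz * sxy + (R_xlen_t)yy * nx + xx;
          if (!visited[w] && mask[w]) {
            visited[w] = 1;
            out[w] = TRUE;
            q.push(w);
          }
        }
      }
    }
  }
  return out;
}

static void flood2d(const std::vector<char>& fg, std::vector<int>& lab,
                    int nx, int ny, int start, int id, bool conn8) {
  std::queue<int> q;
  q.push(start);
  lab[start] = id;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int y = v / nx, x = v - y * nx;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = y + dy; if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        if (!conn8 && dx != 0 && dy != 0) continue;
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        int w = yy * nx + xx;
        if (lab[w] == 0 && fg[w]) { lab[w] = id; q.push(w); }
      }
    }
  }
}

// Largest 8-connected foreground component of a 2-D logical matrix,
// with interior holes filled (background is 4-connected, flooded from
// the matrix border; unreached background pixels are holes).
// [[Rcpp::export(name = ".body_component_2d")]]
LogicalMatrix body_component_2d(LogicalMatrix mask, bool fill_holes) {
  const int nx = mask.nrow(), ny = mask.ncol();
  const int n = nx * ny;
  std::vector<char> fg(n);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      fg[j * nx + i] = mask(i, j) ? 1 : 0;

  // label 8-connected foreground components, remember the largest
  std::vector<int> lab(n, 0);
  int nextId = 0, bestId = 0, bestSize = 0;
  for (int v = 0; v < n; ++v) {
    if (fg[v] && lab[v] == 0) {
      ++nextId;
      flood2d(fg, lab, nx, ny, v, nextId, true);
      int sz = 0;
      for (int w = 0; w < n; ++w) if (lab[w] == nextId) ++sz;
      if (sz > bestSize) { bestSize = sz; bestId = nextId; }
    }
  }
  LogicalMatrix out(nx, ny);
  if (bestId == 0) return out;  // empty input
  std::vector<char> keep(n, 0);
  for (int v = 0; v < n; ++v) keep[v] = (lab[v] == bestId);

  if (fill_holes) {
    // 4-connected flood of the complement of `keep` from the border;
    // complement pixels never reached lie inside the component
    std::vector<char> bg(n), reach(n, 0);
    for (int v = 0; v < n; ++v) bg[v] = !keep[v];
    std::vector<int> blab(n, 0);
    for (int i = 0; i < nx; ++i) {
      int tops[2] = { i, (ny - 1) * nx + i };
      for (int v : tops) if (bg[v] && blab[v] == 0) flood2d(bg, blab, nx, ny, v, 1, false);
    }
    for (int j = 0; j < ny; ++j) {
      int sides[2] = { j * nx, j * nx + nx - 1 };
      for (int v : sides) if (bg[v] && blab[v] == 0) flood2d(bg, blab, nx, ny, v, 1, false);
    }
    for (int v = 0; v < n; ++v) if (bg[v] && blab[v] == 0) keep[v] = 1;
  }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      out(i, j) = keep[j * nx + i] ? TRUE : FALSE;
  return out;
}
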