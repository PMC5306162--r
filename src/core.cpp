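// Low-level voxel kernels: separable convolution, interpolation,
// topology-preserving thinning, connected components, nearest-label
// re-inflation.  All grids are passed as flat vectors in R's
// column-major order with explicit dimensions; voxel coordinates are
// 0-based throughout.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>
#include <climits>

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export(name = ".cpp_convolve_sep")]]
NumericVector cpp_convolve_sep(NumericVector vol, IntegerVector dim,
                               NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  const int kr = klen / 2;  // kernel assumed odd length, centred
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(a.size());
  // axis 0
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int k = 0; k < klen; ++k) {
          int xx = x + k - kr;
          if (xx >= 0 && xx < nx) s += kernel[k] * a[idx3(xx, y, z, nx, ny)];
        }
        b[idx3(x, y, z, nx, ny)] = s;
      }
  // axis 1
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int k = 0; k < klen; ++k) {
          int yy = y + k - kr;
          if (yy >= 0 && yy < ny) s += kernel[k] * b[idx3(x, yy, z, nx, ny)];
        }
        a[idx3(x, y, z, nx, ny)] = s;
      }
  // axis 2
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int k = 0; k < klen; ++k) {
          int zz = z + k - kr;
          if (zz >= 0 && zz < nz) s += kernel[k] * a[idx3(x, y, zz, nx, ny)];
        }
        b[idx3(x, y, z, nx, ny)] = s;
      }
  return NumericVector(b.begin(), b.end());
}

// Trilinear interpolation at 0-based voxel coordinates; outside -> fill.
// [[Rcpp::export(name = ".cpp_sample_trilinear")]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (px < -0.5 || py < -0.5 || pz < -0.5 ||
        px > nx - 0.5 || py > ny - 0.5 || pz > nz - 0.5) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
        z0 = (int)std::floor(pz);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    double s = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
          double v = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 &&
                      zz < nz)
                         ? vol[idx3(xx, yy, zz, nx, ny)]
                         : fill;
          s += w * v;
        }
    out[i] = s;
  }
  return out;
}

// Nearest-neighbour sampling (used for label volumes); outside -> fill.
// [[Rcpp::export(name = ".cpp_sample_nearest")]]
NumericVector cpp_sample_nearest(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int x = (int)std::floor(pts(i, 0) + 0.5);
    int y = (int)std::floor(pts(i, 1) + 0.5);
    int z = (int)std::floor(pts(i, 2) + 0.5);
    out[i] = (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
                 ? vol[idx3(x, y, z, nx, ny)]
                 : fill;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point machinery (Bertrand/Malandain topological numbers).
// A foreground voxel is simple iff removing it changes neither the
// number of 26-connected foreground components nor the number of
// 6-connected background components locally:
//   T26 = number of 26-components of the foreground 26-neighbourhood == 1
//   T6  = number of 6-components of the background 18-neighbourhood that
//         touch a face neighbour of the centre == 1
// ---------------------------------------------------------------------------

// cube positions: p = (dx+1) + 3*((dy+1) + 3*(dz+1)), centre p == 13
static inline void p2d(int p, int &dx, int &dy, int &dz) {
  dx = p % 3 - 1;
  dy = (p / 3) % 3 - 1;
  dz = p / 9 - 1;
}

static bool is_simple(const std::vector<char> &grid, int x, int y, int z,
                      int nx, int ny, int nz) {
  char nb[27];
  for (int p = 0; p < 27; ++p) {
    int dx, dy, dz;
    p2d(p, dx, dy, dz);
    int xx = x + dx, yy = y + dy, zz = z + dz;
    nb[p] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
                ? grid[idx3(xx, yy, zz, nx, ny)]
                : 0;
  }
  // T26: 26-components of foreground within the 26-neighbourhood
  int comp[27];
  for (int p = 0; p < 27; ++p) comp[p] = -1;
  int ncomp26 = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || comp[p] >= 0) continue;
    // BFS
    std::queue<int> q;
    q.push(p);
    comp[p] = ncomp26;
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      int ux, uy, uz;
      p2d(u, ux, uy, uz);
      for (int v = 0; v < 27; ++v) {
        if (v == 13 || !nb[v] || comp[v] >= 0) continue;
        int vx, vy, vz;
        p2d(v, vx, vy, vz);
        if (std::abs(ux - vx) <= 1 && std::abs(uy - vy) <= 1 &&
            std::abs(uz - vz) <= 1)
          comp[v] = ncomp26, q.push(v);
      }
    }
    ++ncomp26;
  }
  if (ncomp26 != 1) return false;
  // T6: 6-components of background within the 18-neighbourhood,
  // seeded from (and restricted to reachability via) face neighbours
  bool in18[27];
  for (int p = 0; p < 27; ++p) {
    int dx, dy, dz;
    p2d(p, dx, dy, dz);
    int nz_ = (dx != 0) + (dy != 0) + (dz != 0);
    in18[p] = (p != 13) && nz_ <= 2;
  }
  for (int p = 0; p < 27; ++p) comp[p] = -1;
  int ncomp6 = 0;
  static const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  for (int f = 0; f < 6; ++f) {
    int p = face[f];
    if (nb[p] || comp[p] >= 0) continue;
    std::queue<int> q;
    q.push(p);
    comp[p] = ncomp6;
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      int ux, uy, uz;
      p2d(u, ux, uy, uz);
      for (int v = 0; v < 27; ++v) {
        if (!in18[v] || nb[v] || comp[v] >= 0) continue;
        int vx, vy, vz;
        p2d(v, vx, vy, vz);
        int d = std::abs(ux - vx) + std::abs(uy - vy) + std::abs(uz - vz);
        if (d == 1) comp[v] = ncomp6, q.push(v);
      }
    }
    ++ncomp6;
  }
  return ncomp6 == 1;
}

static int count_neighbours26(const std::vector<char> &grid, int x, int y,
                              int z, int nx, int ny, int nz) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz &&
            grid[idx3(xx, yy, zz, nx, ny)])
          ++c;
      }
  return c;
}

// Sequential topology-preserving thinning with 6 directional
// sub-iterations.  In each sub-iteration only voxels whose face
// neighbour in the current direction is background are candidates;
// candidates are deleted one at a time if still simple and not a curve
// endpoint at the moment of deletion.  Every deletion is a simple
// point, so topology is preserved exactly; cycling the six directions
// peels surfaces symmetrically so the residue tracks the medial axis
// and thin structures do not erode lengthwise.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> grid(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) grid[i] = mask[i] ? 1 : 0;
  static const int fdx[6] = {-1, 1, 0, 0, 0, 0};
  static const int fdy[6] = {0, 0, -1, 1, 0, 0};
  static const int fdz[6] = {0, 0, 0, 0, -1, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      // a candidate has background at its `dir` face and foreground at
      // the opposite face: a genuine border voxel of this direction
      // (the opposite-face condition stops one-voxel-thick structures
      // from eroding lengthwise during an orthogonal sub-iteration)
      auto is_cand = [&](int x, int y, int z) {
        int xx = x + fdx[dir], yy = y + fdy[dir], zz = z + fdz[dir];
        bool bg = xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                  zz >= nz || !grid[idx3(xx, yy, zz, nx, ny)];
        if (!bg) return false;
        int ox = x - fdx[dir], oy = y - fdy[dir], oz = z - fdz[dir];
        return ox >= 0 && ox < nx && oy >= 0 && oy < ny && oz >= 0 &&
               oz < nz && grid[idx3(ox, oy, oz, nx, ny)] != 0;
      };
      std::vector<int> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = idx3(x, y, z, nx, ny);
            if (grid[i] && is_cand(x, y, z)) cand.push_back(i);
          }
      for (size_t b = 0; b < cand.size(); ++b) {
        int i = cand[b];
        if (!grid[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        if (!is_cand(x, y, z)) continue;  // re-check on the current grid
        int nnb = count_neighbours26(grid, x, y, z, nx, ny, nz);
        if (nnb <= 1) continue;  // endpoint or isolated voxel: protect
        if (is_simple(grid, x, y, z, nx, ny, nz)) {
          grid[i] = 0;
          changed = true;
        }
      }
    }
  }
  // cleanup: the residue is now at most one voxel thick, where an
  // unrestricted sequential pass is safe (removing a voxel of a clean
  // digital curve disconnects it, hence is not simple); this strips
  // redundant staircase voxels that the directional passes keep
  changed = true;
  while (changed) {
    changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (!grid[i]) continue;
          int nnb = count_neighbours26(grid, x, y, z, nx, ny, nz);
          if (nnb <= 1) continue;
          if (is_simple(grid, x, y, z, nx, ny, nz)) {
            grid[i] = 0;
            changed = true;
          }
        }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = grid[i] != 0;
  return out;
}

// Connected-component labelling, connectivity 6 or 26.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && d != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    std::queue<int> q;
    q.push((int)s);
    lab[s] = cur;
    while (!q.empty()) {
      int i = q.front();
      q.pop();
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int xx = x + offs[o][0], yy = y + offs[o][1], zz = z + offs[o][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && !lab[j]) {
          lab[j] = cur;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// Constrained nearest-label dilation: every mask voxel within Chebyshev
// radius of a labelled voxel takes the label of the Euclidean-nearest
// labelled voxel (ties -> lower label id); everything else stays 0.
// [[Rcpp::export(name = ".cpp_reinflate")]]
IntegerVector cpp_reinflate(IntegerVector labels, LogicalVector mask,
                            IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(labels.size(), 0);
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s]) continue;
    int x = s % nx, y = (s / nx) % ny, z = s / (nx * ny);
    int best_lab = 0;
    int best_d2 = INT_MAX;
    for (int dz = -radius; dz <= radius; ++dz)
      for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int l = labels[idx3(xx, yy, zz, nx, ny)];
          if (l <= 0) continue;
          int d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best_d2 || (d2 == best_d2 && l < best_lab)) {
            best_d2 = d2;
            best_lab = l;
          }
        }
    out[s] = best_lab;
  }
  return out;
}

// Undirected 26-adjacency edge list between foreground voxels,
// as 0-based linear indices (each pair once, i < j).
// [[Rcpp::export(name = ".cpp_adjacency_edges")]]
List cpp_adjacency_edges(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> from, to;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i]) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = (dz ? -1 : 0); dy <= 1; ++dy)
        for (int dx = (dz || dy ? -1 : 1); dx <= 1; ++dx) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
              zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (mask[j]) {
            from.push_back((int)i);
            to.push_back(j);
          }
        }
  }
  return List::create(_["from"] = IntegerVector(from.begin(), from.end()),
                      _["to"] = IntegerVector(to.begin(), to.end()));
}

// 26-neighbour counts for a voxel set (skeleton graph support).
// [[Rcpp::export(name = ".cpp_neighbour_counts")]]
IntegerVector cpp_neighbour_counts(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> grid(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) grid[i] = mask[i] ? 1 : 0;
  IntegerVector out(mask.size(), 0);
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!grid[i]) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    out[i] = count_neighbours26(grid, x, y, z, nx, ny, nz);
  }
  return out;
}
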