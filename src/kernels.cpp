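#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Voxel indexing is 0-based (x, y, z) on a column-major array with
// dims (nx, ny, nz): linear index = x + nx * (y + ny * z).

namespace {

struct Grid {
  int nx, ny, nz;
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
  }
};

// Neighbor offsets in fixed lexicographic (dz, dy, dx) order, zero excluded.
// The shared ordering keeps every flood / traversal deterministic.
static void offsets26(std::vector<int>& dx, std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        if (x == 0 && y == 0 && z == 0) continue;
        dx.push_back(x); dy.push_back(y); dz.push_back(z);
      }
}

// 6-neighborhood in the same (dz, dy, dx) lexicographic order.
static void offsets6(std::vector<int>& dx, std::vector<int>& dy, std::vector<int>& dz) {
  std::vector<int> ax, ay, az;
  offsets26(ax, ay, az);
  dx.clear(); dy.clear(); dz.clear();
  for (size_t i = 0; i < ax.size(); ++i) {
    if (std::abs(ax[i]) + std::abs(ay[i]) + std::abs(az[i]) == 1) {
      dx.push_back(ax[i]); dy.push_back(ay[i]); dz.push_back(az[i]);
    }
  }
}

// --- simple-point machinery (Bertrand/Malandain characterization) -----------
//
// A foreground voxel is simple iff deleting it preserves the topology of both
// the 26-connected foreground and the 6-connected background:
//   (a) the foreground restricted to its 26-neighborhood (center excluded)
//       has exactly one 26-connected component, and
//   (b) the background restricted to its 18-neighborhood has exactly one
//       6-connected component that touches a face neighbor of the center.

// nb[27]: local 3x3x3 foreground flags in (dx,dy,dz) in {-1,0,1}, index
// (dx+1) + 3*((dy+1) + 3*(dz+1)); center at 13.
static int count_fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    std::vector<int> stack(1, i);
    seen[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int z = cz - 1; z <= cz + 1; ++z)
        for (int y = cy - 1; y <= cy + 1; ++y)
          for (int x = cx - 1; x <= cx + 1; ++x) {
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int j = x + 3 * (y + 3 * z);
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true;
            stack.push_back(j);
          }
    }
  }
  return comps;
}

static int count_bg_components6(const bool nb[27]) {
  // restrict to the 18-neighborhood (offsets with at most two nonzero coords)
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    in18[i] = (i != 13) && (std::abs(x) + std::abs(y) + std::abs(z) <= 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || seen[i]) continue;
    // flood this background component under 6-connectivity within N18
    bool touches_face = false;
    std::vector<int> stack(1, i);
    seen[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      if (std::abs(cx) + std::abs(cy) + std::abs(cz) == 1) touches_face = true;
      const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int s = 0; s < 6; ++s) {
        int x = cx + step[s][0], y = cy + step[s][1], z = cz + step[s][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int j = (x + 1) + 3 * ((y + 1) + 3 * (z + 1));
        if (!in18[j] || nb[j] || seen[j]) continue;
        seen[j] = true;
        stack.push_back(j);
      }
    }
    if (touches_face) ++comps;
  }
  return comps;
}

static void fill_neighborhood(const int* fg, const Grid& g, int x, int y, int z,
                              bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int j = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[j] = g.inside(xx, yy, zz) && fg[g.idx(xx, yy, zz)];
      }
}

static bool is_simple(const int* fg, const Grid& g, int x, int y, int z) {
  bool nb[27];
  fill_neighborhood(fg, g, x, y, z, nb);
  if (count_fg_components26(nb) != 1) return false;
  return count_bg_components6(nb) == 1;
}

static int fg_neighbor_count26(const int* fg, const Grid& g, int x, int y, int z) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (g.inside(xx, yy, zz) && fg[g.idx(xx, yy, zz)]) ++n;
      }
  return n;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  Grid g{dim[0], dim[1], dim[2]};
  std::vector<int> dx, dy, dz;
  if (connectivity == 6) offsets6(dx, dy, dz); else offsets26(dx, dy, dz);
  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i = g.idx(x, y, z);
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.assign(1, i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          int cx = (int)(c % g.nx);
          int cy = (int)((c / g.nx) % g.ny);
          int cz = (int)(c / ((R_xlen_t)g.nx * g.ny));
          for (size_t k = 0; k < dx.size(); ++k) {
            int xx = cx + dx[k], yy = cy + dy[k], zz = cz + dz[k];
            if (!g.inside(xx, yy, zz)) continue;
            R_xlen_t j = g.idx(xx, yy, zz);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  return labels;
}

// Seeded region growing with a running-mean acceptance rule: a candidate
// voxel v is accepted iff |I(v) - mu| <= tol, where mu is the mean intensity
// of all voxels accepted so far; mu is updated after each acceptance.
// Candidates are tested once, in FIFO order, for determinism.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerVector seed, double tol, int connectivity) {
  Grid g{dim[0], dim[1], dim[2]};
  std::vector<int> dx, dy, dz;
  if (connectivity == 26) offsets26(dx, dy, dz); else offsets6(dx, dy, dz);
  LogicalVector out(vol.size(), false);
  std::vector<char> seen((size_t)vol.size(), 0);
  std::queue<R_xlen_t> q;
  R_xlen_t s = g.idx(seed[0], seed[1], seed[2]);
  out[s] = true;
  seen[(size_t)s] = 1;
  double mu = vol[s];
  double nacc = 1.0;
  q.push(s);
  while (!q.empty()) {
    R_xlen_t c = q.front(); q.pop();
    int cx = (int)(c % g.nx);
    int cy = (int)((c / g.nx) % g.ny);
    int cz = (int)(c / ((R_xlen_t)g.nx * g.ny));
    for (size_t k = 0; k < dx.size(); ++k) {
      int xx = cx + dx[k], yy = cy + dy[k], zz = cz + dz[k];
      if (!g.inside(xx, yy, zz)) continue;
      R_xlen_t j = g.idx(xx, yy, zz);
      if (seen[(size_t)j]) continue;
      seen[(size_t)j] = 1;
      if (std::fabs(vol[j] - mu) <= tol) {
        out[j] = true;
        mu = (mu * nacc + vol[j]) / (nacc + 1.0);
        nacc += 1.0;
        q.push(j);
      }
    }
  }
  return out;
}

// Topology-preserving curve thinning: sequential deletion of simple,
// non-endpoint border voxels in six directional subiterations, repeated to
// stability. Sequential re-testing at deletion time guarantees that both the
// 26-connected foreground and the 6-connected background component structure
// are preserved exactly; endpoints (<= 1 foreground 26-neighbor) are kept so
// curve extremities survive.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  Grid g{dim[0], dim[1], dim[2]};
  R_xlen_t n = mask.size();
  std::vector<int> fg((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) fg[(size_t)i] = mask[i] ? 1 : 0;
  // direction order: +z, -z, +y, -y, +x, -x
  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y)
          for (int x = 0; x < g.nx; ++x) {
            R_xlen_t i = g.idx(x, y, z);
            if (!fg[(size_t)i]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            bool border = !g.inside(xx, yy, zz) || !fg[g.idx(xx, yy, zz)];
            if (border) cand.push_back(i);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        R_xlen_t i = cand[k];
        if (!fg[(size_t)i]) continue;
        int x = (int)(i % g.nx);
        int y = (int)((i / g.nx) % g.ny);
        int z = (int)(i / ((R_xlen_t)g.nx * g.ny));
        if (fg_neighbor_count26(fg.data(), g, x, y, z) < 2) continue; // endpoint
        if (!is_simple(fg.data(), g, x, y, z)) continue;
        fg[(size_t)i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[(size_t)i] != 0;
  return out;
}
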