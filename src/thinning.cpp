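// Topology-preserving 3D curve thinning for binary vessel volumes.
//
// Sequential 6-subiteration border thinning: in each pass, for each of the
// six face directions, border voxels that are simple points (deletable
// without changing topology) and not curve endpoints are removed one at a
// time, re-checking simplicity before each deletion.  Simplicity uses the
// Bertrand-Malandain characterization for (26, 6) connectivity:
//   * exactly one 26-connected foreground component in N26(p), and
//   * exactly one 6-connected background component in N18(p) that is
//     6-adjacent to p.
// Sequential re-checking makes every individual deletion topology-safe, so
// the fixed point is a one-voxel-wide medial curve with the same number of
// connected components, tunnels and cavities as the input.

#include <Rcpp.h>
using namespace Rcpp;

static inline int off_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1); // 0..26, center = 13
}

// gather the 3x3x3 neighborhood of (x,y,z); out-of-bounds counts background
static void neighborhood(const LogicalVector &v, int x, int y, int z,
                         int nx, int ny, int nz, int nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[k] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 &&
                 zz < nz && v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)])
                    ? 1
                    : 0;
      }
}

static inline void unpack(int k, int &dx, int &dy, int &dz) {
  dx = k % 3 - 1;
  dy = (k / 3) % 3 - 1;
  dz = k / 9 - 1;
}

// number of foreground 26-components in N26(p) (center excluded)
static int fg_components26(const int nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz;
      unpack(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb[t]) continue;
        int tx, ty, tz;
        unpack(t, tx, ty, tz);
        if (abs(tx - cx) <= 1 && abs(ty - cy) <= 1 && abs(tz - cz) <= 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp;
}

// number of background 6-components within N18(p) touching a face neighbor
static int bg_components6(const int nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    int sx, sy, sz;
    unpack(s, sx, sy, sz);
    int man = abs(sx) + abs(sy) + abs(sz);
    if (man != 1)  // seeds are the 6 face neighbors
      continue;
    if (nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx, cy, cz;
      unpack(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || nb[t]) continue;
        int tx, ty, tz;
        unpack(t, tx, ty, tz);
        if (abs(tx) + abs(ty) + abs(tz) > 2) continue; // stay within N18
        if (abs(tx - cx) + abs(ty - cy) + abs(tz - cz) == 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp;
}

static inline bool is_simple(const int nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

static inline int n26_count(const int nb[27]) {
  int n = 0;
  for (int k = 0; k < 27; ++k)
    if (k != 13 && nb[k]) ++n;
  return n;
}

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector vol, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != vol.size()) stop("dim does not match volume");
  LogicalVector v = clone(vol);

  const int dirs[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                          {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
  int nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (!v[i]) continue;
            int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
            bool border =
                !(bx >= 0 && bx < nx && by >= 0 && by < ny && bz >= 0 &&
                  bz < nz &&
                  v[bx + (R_xlen_t)nx * (by + (R_xlen_t)ny * bz)]);
            if (!border) continue;
            neighborhood(v, x, y, z, nx, ny, nz, nb);
            if (n26_count(nb) <= 1) continue; // endpoint: keep curve ends
            if (is_simple(nb)) cand.push_back((int)i);
          }
      for (size_t c = 0; c < cand.size(); ++c) {
        R_xlen_t i = cand[c];
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        neighborhood(v, x, y, z, nx, ny, nz, nb);
        if (n26_count(nb) <= 1) continue;
        if (is_simple(nb)) {
          v[i] = FALSE;
          changed = true;
        }
      }
    }
  }
  return v;
}
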