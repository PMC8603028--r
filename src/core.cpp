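// Low-level 3D voxel routines shared by the segmentation, skeleton and trait
// modules. Volumes arrive as logical/numeric vectors in R array order
// (x fastest, then y, then z); dims = c(nx, ny, nz).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Connected component labelling (6- or 26-connectivity).
// Scan order is z, then y, then x so that component ids are assigned in
// increasing (z, y, x) of their seed voxel — a documented deterministic
// tie-break for "keep the largest component".
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
          for (auto &o : offs) {
            int xx = cx + o[0], yy = cy + o[1], zz = cz + o[2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("n") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower envelopes along each axis. Distance of object voxels to
// the nearest background voxel, in voxel units.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt")]]
NumericVector edt(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e18;
  NumericVector D(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) D[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = D[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) D[idx3(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = D[idx3(x, y, z, nx, ny)];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) D[idx3(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = D[idx3(x, y, z, nx, ny)];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; ++z) D[idx3(x, y, z, nx, ny)] = d[z];
    }
  for (R_xlen_t i = 0; i < D.size(); ++i) D[i] = std::sqrt(D[i]);
  return D;
}

// ---------------------------------------------------------------------------
// Topology-preserving curve thinning.
// A border voxel is deleted when it is a simple point for the (26, 6)
// adjacency pair (object 26-connected, background 6-connected) and not a
// curve endpoint. Deletion proceeds in 6 directional subiterations with
// sequential re-checking, which keeps the result one voxel wide and centred.
static const int N26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};

static bool adj26(const int *a, const int *b) {
  return std::abs(a[0]-b[0]) <= 1 && std::abs(a[1]-b[1]) <= 1 &&
         std::abs(a[2]-b[2]) <= 1;
}
static bool adj6(const int *a, const int *b) {
  return std::abs(a[0]-b[0]) + std::abs(a[1]-b[1]) + std::abs(a[2]-b[2]) == 1;
}

// neighbourhood occupancy nb[26]; is the centre voxel simple?
static bool is_simple(const bool nb[26]) {
  // Condition 1: object voxels of N26 form exactly one 26-component.
  int first = -1, cnt = 0;
  for (int i = 0; i < 26; ++i) if (nb[i]) { ++cnt; if (first < 0) first = i; }
  if (cnt == 0) return false;
  bool vis[26] = {false};
  std::vector<int> st; st.push_back(first); vis[first] = true;
  int seen = 1;
  while (!st.empty()) {
    int c = st.back(); st.pop_back();
    for (int j = 0; j < 26; ++j)
      if (nb[j] && !vis[j] && adj26(N26[c], N26[j])) {
        vis[j] = true; ++seen; st.push_back(j);
      }
  }
  if (seen != cnt) return false;
  // Condition 2: background voxels of N18 that are 6-adjacent to the centre
  // form exactly one 6-component within N18.
  int n18[18], n6idx[6], n18cnt = 0, n6cnt = 0;
  for (int i = 0; i < 26; ++i) {
    int man = std::abs(N26[i][0]) + std::abs(N26[i][1]) + std::abs(N26[i][2]);
    if (man <= 2) n18[n18cnt++] = i;
    if (man == 1) n6idx[n6cnt++] = i;
  }
  int start = -1;
  for (int k = 0; k < 6; ++k) if (!nb[n6idx[k]]) { start = n6idx[k]; break; }
  if (start < 0) return false; // interior voxel
  bool vis2[26] = {false};
  st.clear(); st.push_back(start); vis2[start] = true;
  while (!st.empty()) {
    int c = st.back(); st.pop_back();
    for (int k = 0; k < n18cnt; ++k) {
      int j = n18[k];
      if (!nb[j] && !vis2[j] && adj6(N26[c], N26[j])) {
        vis2[j] = true; st.push_back(j);
      }
    }
  }
  for (int k = 0; k < 6; ++k)
    if (!nb[n6idx[k]] && !vis2[n6idx[k]]) return false;
  return true;
}

// [[Rcpp::export(name = ".thin")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<uint8_t> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;
  auto at = [&](int x, int y, int z) -> uint8_t {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return m[idx3(x, y, z, nx, ny)];
  };
  auto fill_nb = [&](int x, int y, int z, bool nb[26]) {
    for (int i = 0; i < 26; ++i)
      nb[i] = at(x + N26[i][0], y + N26[i][1], z + N26[i][2]) != 0;
  };
  auto ncount = [&](const bool nb[26]) {
    int c = 0; for (int i = 0; i < 26; ++i) if (nb[i]) ++c; return c;
  };
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool changed = true;
  std::vector<int> cand;
  bool nb[26];
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = idx3(x, y, z, nx, ny);
            if (!m[i]) continue;
            if (at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            fill_nb(x, y, z, nb);
            int nc = ncount(nb);
            if (nc <= 1) continue;           // endpoint or isolated
            if (is_simple(nb)) cand.push_back(i);
          }
      for (int i : cand) {
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        fill_nb(x, y, z, nb);
        int nc = ncount(nb);
        if (nc <= 1) continue;
        if (is_simple(nb)) { m[i] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Local 2x2x2 configuration census for the calibrated surface area estimator.
// For each cell of the (implicitly zero-padded) mask, an 8-bit configuration
// is formed (bit order: x fastest, then y, then z inside the cell). The cell
// is mapped to a canonical class by `canon` (256-entry table built in R).
// The 2-adjacent-corner class is split by local context into sharp-edge
// cells (no same-class face neighbour perpendicular to the corner-pair axis)
// and 45-degree sheet cells. Returns counts per feature as named in R.
// pax: 256-entry table, axis (0=x,1=y,2=z) of the minority corner pair, or -1.
// [[Rcpp::export(name = ".surface_cells")]]
IntegerVector surface_cells(LogicalVector mask, IntegerVector dims,
                            IntegerVector canon, IntegerVector pax,
                            int edge_class) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return mask[idx3(x, y, z, nx, ny)] ? 1 : 0;
  };
  // cell grid spans (-1..nx-1) x (-1..ny-1) x (-1..nz-1) cell origins
  const int cx = nx + 1, cy = ny + 1, cz = nz + 1;
  std::vector<int16_t> cls(static_cast<size_t>(cx) * cy * cz, -2);
  std::vector<int8_t> axv(static_cast<size_t>(cx) * cy * cz, -1);
  auto cidx = [&](int x, int y, int z) {
    return static_cast<size_t>(x + 1) +
           static_cast<size_t>(cx) * ((y + 1) + static_cast<size_t>(cy) * (z + 1));
  };
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        int cfg = 0, b = 0;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx, ++b)
              if (at(x + dx, y + dy, z + dz)) cfg |= (1 << b);
        cls[cidx(x, y, z)] = (int16_t)canon[cfg];
        axv[cidx(x, y, z)] = (int8_t)pax[cfg];
      }
  // counts indexed by canonical class id 0..255 plus two context slots
  IntegerVector out(258, 0); // out[c] for class c; out[256] edge, out[257] sheet
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        int c = cls[cidx(x, y, z)];
        if (c <= 0) continue;
        if (c != edge_class) { out[c] += 1; continue; }
        int ax = axv[cidx(x, y, z)];
        bool sheet = false;
        if (ax >= 0) {
          const int fdirs[3][2][3] = {
            {{0,1,0},{0,0,1}}, {{1,0,0},{0,0,1}}, {{1,0,0},{0,1,0}}};
          // pair axis ax: perpendicular face directions are the other two axes
          for (int k = 0; k < 2 && !sheet; ++k) {
            const int *dv = fdirs[ax][k];
            for (int s = -1; s <= 1 && !sheet; s += 2) {
              int xx = x + s * dv[0], yy = y + s * dv[1], zz = z + s * dv[2];
              if (xx < -1 || yy < -1 || zz < -1 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              if (cls[cidx(xx, yy, zz)] == edge_class) sheet = true;
            }
          }
        }
        out[sheet ? 257 : 256] += 1;
      }
  return out;
}

// ---------------------------------------------------------------------------
// 3D convex hull volume by incremental construction (quickhull-style visible
// face deletion). Points in physical coordinates, rows of `pts`.
// Returns the hull volume (0 for degenerate/coplanar input).
struct Face { int a, b, c; double nxv, nyv, nzv, off; bool alive; };

static void face_plane(Face &f, const std::vector<double> &X,
                       const std::vector<double> &Y, const std::vector<double> &Z) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nxv = uy * vz - uz * vy;
  f.nyv = uz * vx - ux * vz;
  f.nzv = ux * vy - uy * vx;
  f.off = f.nxv * X[f.a] + f.nyv * Y[f.a] + f.nzv * Z[f.a];
}

// [[Rcpp::export(name = ".hull3d_volume")]]
double hull3d_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i,0); Y[i] = pts(i,1); Z[i] = pts(i,2); }
  // scale-aware tolerance
  double span = 0;
  for (int i = 0; i < n; ++i) {
    span = std::max(span, std::abs(X[i]));
    span = std::max(span, std::abs(Y[i]));
    span = std::max(span, std::abs(Z[i]));
  }
  const double eps = 1e-9 * std::max(1.0, span * span);
  // initial simplex: extreme pair, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) { if (X[i] < X[i0]) i0 = i; if (X[i] > X[i1]) i1 = i; }
  if (i0 == i1) { for (int i = 1; i < n; ++i) { if (Y[i] < Y[i0]) i0 = i; if (Y[i] > Y[i1]) i1 = i; } }
  if (i0 == i1) { for (int i = 1; i < n; ++i) { if (Z[i] < Z[i0]) i0 = i; if (Z[i] > Z[i1]) i1 = i; } }
  if (i0 == i1) return 0.0;
  double dx = X[i1]-X[i0], dy = Y[i1]-Y[i0], dz = Z[i1]-Z[i0];
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double px = X[i]-X[i0], py = Y[i]-Y[i0], pz = Z[i]-Z[i0];
    double cxv = dy*pz - dz*py, cyv = dz*px - dx*pz, czv = dx*py - dy*px;
    double d2 = cxv*cxv + cyv*cyv + czv*czv;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0) return 0.0;
  Face f0{i0, i1, i2, 0,0,0,0,true};
  face_plane(f0, X, Y, Z);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::abs(f0.nxv*X[i] + f0.nyv*Y[i] + f0.nzv*Z[i] - f0.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return 0.0; // coplanar
  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c, double ix, double iy, double iz) {
    Face f{a, b, c, 0,0,0,0,true};
    face_plane(f, X, Y, Z);
    // orient outward w.r.t. interior point
    if (f.nxv*ix + f.nyv*iy + f.nzv*iz > f.off) {
      std::swap(f.b, f.c); face_plane(f, X, Y, Z);
    }
    faces.push_back(f);
  };
  double ix = (X[i0]+X[i1]+X[i2]+X[i3]) / 4.0;
  double iy = (Y[i0]+Y[i1]+Y[i2]+Y[i3]) / 4.0;
  double iz = (Z[i0]+Z[i1]+Z[i2]+Z[i3]) / 4.0;
  add_face(i0,i1,i2, ix,iy,iz); add_face(i0,i1,i3, ix,iy,iz);
  add_face(i0,i2,i3, ix,iy,iz); add_face(i1,i2,i3, ix,iy,iz);
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // find visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = faces[f].nxv*X[p] + faces[f].nyv*Y[p] + faces[f].nzv*Z[p] - faces[f].off;
      if (d > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon edges: edges of visible faces not shared with another visible face
    std::map<std::pair<int,int>, int> edgecnt;
    auto key = [](int a, int b) {
      return a < b ? std::make_pair(a,b) : std::make_pair(b,a);
    };
    for (int f : vis) {
      edgecnt[key(faces[f].a, faces[f].b)]++;
      edgecnt[key(faces[f].b, faces[f].c)]++;
      edgecnt[key(faces[f].c, faces[f].a)]++;
    }
    for (int f : vis) faces[f].alive = false;
    for (auto &e : edgecnt)
      if (e.second == 1)
        add_face(e.first.first, e.first.second, p, ix, iy, iz);
  }
  // volume via signed tetrahedra against the interior point
  double vol = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    double ax = X[f.a]-ix, ay = Y[f.a]-iy, az = Z[f.a]-iz;
    double bx = X[f.b]-ix, by = Y[f.b]-iy, bz = Z[f.b]-iz;
    double cxv = X[f.c]-ix, cyv = Y[f.c]-iy, czv = Z[f.c]-iz;
    double det = ax*(by*czv - bz*cyv) - ay*(bx*czv - bz*cxv) + az*(bx*cyv - by*cxv);
    vol += std::abs(det) / 6.0;
  }
  return vol;
}

// ---------------------------------------------------------------------------
// Rasterize spheres (tube cross-sections sampled along centrelines) into a
// logical mask. Centres in 1-based voxel coordinates, radii in voxels.
// [[Rcpp::export(name = ".stamp_spheres")]]
LogicalVector stamp_spheres(NumericMatrix centers, NumericVector radii,
                            IntegerVector dims, LogicalVector init) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector m = clone(init);
  for (int k = 0; k < centers.nrow(); ++k) {
    double cxv = centers(k,0), cyv = centers(k,1), czv = centers(k,2);
    double r = radii[k];
    int x0 = std::max(0, (int)std::floor(cxv - r - 1.5));
    int x1 = std::min(nx - 1, (int)std::ceil(cxv + r - 0.5));
    int y0 = std::max(0, (int)std::floor(cyv - r - 1.5));
    int y1 = std::min(ny - 1, (int)std::ceil(cyv + r - 0.5));
    int z0 = std::max(0, (int)std::floor(czv - r - 1.5));
    int z1 = std::min(nz - 1, (int)std::ceil(czv + r - 0.5));
    double r2 = r * r;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double dx = (x + 1) - cxv, dy = (y + 1) - cyv, dz = (z + 1) - czv;
          if (dx*dx + dy*dy + dz*dz <= r2)
            m[idx3(x, y, z, nx, ny)] = true;
        }
  }
  return m;
}

// ---------------------------------------------------------------------------
// 26-neighbour degree of every voxel of a mask (used for skeleton node
// classification), and neighbour lists for path tracing done in R.
// [[Rcpp::export(name = ".neighbor_degree")]]
IntegerVector neighbor_degree(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector deg(mask.size(), 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        int c = 0;
        for (int k = 0; k < 26; ++k) {
          int xx = x + N26[k][0], yy = y + N26[k][1], zz = z + N26[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          if (mask[idx3(xx, yy, zz, nx, ny)]) ++c;
        }
        deg[i] = c;
      }
  return deg;
}
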