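// Low-level voxel/mesh kernels: 3D connected-component labelling, exact
// Euclidean distance transform, marching-tetrahedra isosurfacing and a
// Dijkstra geodesic tracer used for centerline extraction.
#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cstdint>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// [[Rcpp::export(name = ".cw_label_components")]]
IntegerVector cw_label_components(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        nb.push_back({dx, dy, dz});
      }

  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int k = cur / (nx * ny);
      int r = cur - k * nx * ny;
      int j = r / nx;
      int i = r - j * nx;
      for (auto &d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int t = idx3(ii, jj, kk, nx, ny);
        if (mask[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with grid step w
static void dt1d(std::vector<double> &f, std::vector<double> &d, double w2) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Distance (mm) from every voxel to the nearest background (FALSE) voxel.
// With border_bg != 0 voxels outside the grid count as background (bounded
// transform); otherwise the grid border is no constraint, so e.g. a vessel
// leaving the field of view keeps its true caliber at the boundary face.
// [[Rcpp::export(name = ".cw_edt")]]
NumericVector cw_edt(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing, int border_bg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  NumericVector g(n);
  for (R_xlen_t s = 0; s < n; ++s) g[s] = mask[s] ? INF : 0.0;

  // pass along x
  {
    std::vector<double> f(nx + 2), d(nx + 2);
    double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        f[0] = border_bg ? 0.0 : INF; f[nx + 1] = f[0];
        for (int i = 0; i < nx; ++i) f[i + 1] = g[idx3(i, j, k, nx, ny)];
        dt1d(f, d, w2);
        for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i + 1];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny + 2), d(ny + 2);
    double w2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        f[0] = border_bg ? 0.0 : INF; f[ny + 1] = f[0];
        for (int j = 0; j < ny; ++j) f[j + 1] = g[idx3(i, j, k, nx, ny)];
        dt1d(f, d, w2);
        for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j + 1];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz + 2), d(nz + 2);
    double w2 = spacing[2] * spacing[2];
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        f[0] = border_bg ? 0.0 : INF; f[nz + 1] = f[0];
        for (int k = 0; k < nz; ++k) f[k + 1] = g[idx3(i, j, k, nx, ny)];
        dt1d(f, d, w2);
        for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k + 1];
      }
  }
  for (R_xlen_t s = 0; s < n; ++s) g[s] = std::sqrt(g[s]);
  g.attr("dim") = dims;
  return g;
}

// ---- marching tetrahedra -------------------------------------------------
// Kuhn subdivision of every grid cube into 6 tetrahedra (paths from the cube
// corner (0,0,0) to (1,1,1) through the 6 axis permutations). The subdivision
// induces the same diagonal on the shared face of adjacent cubes, so the
// triangulated isosurface is watertight. The field is padded with a border of
// `pad_value` (below iso) so surfaces always close.

struct Key {
  uint64_t a;
  bool operator==(const Key &o) const { return a == o.a; }
};
struct KeyHash {
  size_t operator()(const Key &k) const { return std::hash<uint64_t>()(k.a); }
};

// [[Rcpp::export(name = ".cw_march_tets")]]
List cw_march_tets(NumericVector field, IntegerVector dims, double iso,
                   NumericVector spacing, NumericVector origin,
                   double pad_value) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2, py = ny + 2, pz = nz + 2;

  auto val = [&](int i, int j, int k) -> double {
    // i,j,k are padded-grid coordinates (0..px-1); original voxel = i-1 etc.
    if (i < 1 || j < 1 || k < 1 || i > nx || j > ny || k > nz)
      return pad_value;
    return field[idx3(i - 1, j - 1, k - 1, nx, ny)];
  };

  const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
  };

  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> verts;   // x,y,z triples (physical mm)
  std::vector<int> faces;      // 0-based vertex triples

  auto gidx = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)px * ((uint64_t)j + (uint64_t)py * k);
  };

  // vertex on the edge between padded grid points a and b
  auto edge_vertex = [&](int ai, int aj, int ak, double av,
                         int bi, int bj, int bk, double bv) -> int {
    uint64_t ga = gidx(ai, aj, ak), gb = gidx(bi, bj, bk);
    if (ga > gb) { std::swap(ga, gb); std::swap(ai, bi); std::swap(aj, bj);
                   std::swap(ak, bk); std::swap(av, bv); }
    Key key{ga * 0x100000000ULL ^ gb};
    // combine into a unique 128->64 key: safe because ga,gb < 2^32 here
    key.a = (ga << 32) | (gb & 0xffffffffULL);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - av) / (bv - av);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double x = (ai - 1) + t * (bi - ai);
    double y = (aj - 1) + t * (bj - aj);
    double z = (ak - 1) + t * (bk - ak);
    verts.push_back(origin[0] + x * spacing[0]);
    verts.push_back(origin[1] + y * spacing[1]);
    verts.push_back(origin[2] + z * spacing[2]);
    int id = (int)(verts.size() / 3) - 1;
    vmap.emplace(key, id);
    return id;
  };

  // orientation: outward normal must point away from the inside (>iso) side
  auto push_tri = [&](int v1, int v2, int v3,
                      double ix, double iy, double iz,
                      double ox_, double oy_, double oz_) {
    double ax = verts[3 * v1], ay = verts[3 * v1 + 1], az = verts[3 * v1 + 2];
    double bx = verts[3 * v2], by = verts[3 * v2 + 1], bz = verts[3 * v2 + 2];
    double cx = verts[3 * v3], cy = verts[3 * v3 + 1], cz = verts[3 * v3 + 2];
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double wx = cx - ax, wy = cy - ay, wz = cz - az;
    double nxn = uy * wz - uz * wy;
    double nyn = uz * wx - ux * wz;
    double nzn = ux * wy - uy * wx;
    // direction from inside centroid to outside centroid
    double dx = ox_ - ix, dy = oy_ - iy, dz = oz_ - iz;
    if (nxn * dx + nyn * dy + nzn * dz >= 0) {
      faces.push_back(v1); faces.push_back(v2); faces.push_back(v3);
    } else {
      faces.push_back(v1); faces.push_back(v3); faces.push_back(v2);
    }
  };

  int tp[4][3];
  double tv[4];
  for (int k = 0; k < pz - 1; ++k)
    for (int j = 0; j < py - 1; ++j)
      for (int i = 0; i < px - 1; ++i) {
        // skip cubes fully inside or outside (fast reject on corner values)
        double c[8];
        bool anyIn = false, anyOut = false;
        for (int b = 0; b < 8; ++b) {
          c[b] = val(i + (b & 1), j + ((b >> 1) & 1), k + ((b >> 2) & 1));
          if (c[b] > iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int p = 0; p < 6; ++p) {
          tp[0][0] = i; tp[0][1] = j; tp[0][2] = k;
          for (int s = 0; s < 3; ++s) {
            tp[s + 1][0] = tp[s][0]; tp[s + 1][1] = tp[s][1];
            tp[s + 1][2] = tp[s][2];
            tp[s + 1][perms[p][s]] += 1;
          }
          bool in[4]; int nin = 0;
          for (int s = 0; s < 4; ++s) {
            int b = (tp[s][0] - i) + 2 * (tp[s][1] - j) + 4 * (tp[s][2] - k);
            tv[s] = c[b];
            in[s] = tv[s] > iso;
            if (in[s]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // centroids of the inside / outside tet vertices (mm)
          double icx = 0, icy = 0, icz = 0, ocx = 0, ocy = 0, ocz = 0;
          int ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) {
            double x = origin[0] + (tp[s][0] - 1) * spacing[0];
            double y = origin[1] + (tp[s][1] - 1) * spacing[1];
            double z = origin[2] + (tp[s][2] - 1) * spacing[2];
            if (in[s]) { icx += x; icy += y; icz += z; ++ni; }
            else       { ocx += x; ocy += y; ocz += z; ++no; }
          }
          icx /= ni; icy /= ni; icz /= ni;
          ocx /= no; ocy /= no; ocz /= no;

          int pos[4], neg[4]; int npos = 0, nneg = 0;
          for (int s = 0; s < 4; ++s) {
            if (in[s]) pos[npos++] = s; else neg[nneg++] = s;
          }
          auto EV = [&](int a, int b) {
            return edge_vertex(tp[a][0], tp[a][1], tp[a][2], tv[a],
                               tp[b][0], tp[b][1], tp[b][2], tv[b]);
          };
          if (nin == 1) {
            int a = pos[0];
            int v1 = EV(a, neg[0]), v2 = EV(a, neg[1]), v3 = EV(a, neg[2]);
            push_tri(v1, v2, v3, icx, icy, icz, ocx, ocy, ocz);
          } else if (nin == 3) {
            int a = neg[0];
            int v1 = EV(a, pos[0]), v2 = EV(a, pos[1]), v3 = EV(a, pos[2]);
            push_tri(v1, v2, v3, icx, icy, icz, ocx, ocy, ocz);
          } else {  // 2 in, 2 out -> quad split into two triangles
            int a = pos[0], b = pos[1], cN = neg[0], dN = neg[1];
            int vac = EV(a, cN), vad = EV(a, dN);
            int vbc = EV(b, cN), vbd = EV(b, dN);
            push_tri(vac, vad, vbd, icx, icy, icz, ocx, ocy, ocz);
            push_tri(vac, vbd, vbc, icx, icy, icz, ocx, ocy, ocz);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = verts[3 * v]; V(v, 1) = verts[3 * v + 1];
    V(v, 2) = verts[3 * v + 2];
  }
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = faces[3 * f] + 1; F(f, 1) = faces[3 * f + 1] + 1;
    F(f, 2) = faces[3 * f + 2] + 1;  // 1-based for R
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Geodesic shortest path through a foreground mask, 26-connected, with per
// voxel cost multiplier (e.g. inverse inscribed-sphere radius so the path
// hugs the lumen centerline). start/end are 1-based linear indices.
// [[Rcpp::export(name = ".cw_dijkstra_path")]]
IntegerMatrix cw_dijkstra_path(LogicalVector mask, IntegerVector dims,
                               NumericVector spacing, NumericVector cost,
                               int start, int end) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> prev(n, -1);

  std::vector<std::array<int,3>> nb;
  std::vector<double> step;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        nb.push_back({dx, dy, dz});
        step.push_back(std::sqrt(dx * dx * spacing[0] * spacing[0] +
                                 dy * dy * spacing[1] * spacing[1] +
                                 dz * dz * spacing[2] * spacing[2]));
      }

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  int s0 = start - 1, e0 = end - 1;
  dist[s0] = 0.0;
  pq.push({0.0, s0});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int cur = top.second;
    if (top.first > dist[cur]) continue;
    if (cur == e0) break;
    int k = cur / (nx * ny);
    int r = cur - k * nx * ny;
    int j = r / nx;
    int i = r - j * nx;
    for (size_t q = 0; q < nb.size(); ++q) {
      int ii = i + nb[q][0], jj = j + nb[q][1], kk = k + nb[q][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int t = idx3(ii, jj, kk, nx, ny);
      if (!mask[t]) continue;
      double w = dist[cur] + step[q] * 0.5 * (cost[cur] + cost[t]);
      if (w < dist[t]) { dist[t] = w; prev[t] = cur; pq.push({w, t}); }
    }
  }
  if (!std::isfinite(dist[e0])) return IntegerMatrix(0, 3);
  std::vector<int> path;
  for (int cur = e0; cur != -1; cur = prev[cur]) path.push_back(cur);
  IntegerMatrix P((int)path.size(), 3);
  for (int s = 0; s < (int)path.size(); ++s) {
    int cur = path[(int)path.size() - 1 - s];
    int k = cur / (nx * ny);
    int r = cur - k * nx * ny;
    int j = r / nx;
    int i = r - j * nx;
    P(s, 0) = i + 1; P(s, 1) = j + 1; P(s, 2) = k + 1;
  }
  return P;
}

// binary dilation (op=0) / erosion (op=1) over an explicit offset list
// [[Rcpp::export(name = ".cw_binary_morph")]]
LogicalVector cw_binary_morph(LogicalVector mask, IntegerVector dims,
                              IntegerMatrix offsets, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const int no = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = (op == 1);
        for (int q = 0; q < no; ++q) {
          int ii = i + offsets(q, 0), jj = j + offsets(q, 1),
              kk = k + offsets(q, 2);
          bool v;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            v = (op == 1);  // outside counts as TRUE for erosion, FALSE dilation
          else
            v = mask[idx3(ii, jj, kk, nx, ny)];
          if (op == 0) { if (v) { acc = true; break; } }
          else         { if (!v) { acc = false; break; } }
        }
        out[idx3(i, j, k, nx, ny)] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// 3x3x3 box majority vote (smoothing step of the morphological level set)
// [[Rcpp::export(name = ".cw_box_majority")]]
LogicalVector cw_box_majority(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz) continue;
              if (mask[idx3(ii, jj, kk, nx, ny)]) ++cnt;
            }
        out[idx3(i, j, k, nx, ny)] = cnt > 13;
      }
  out.attr("dim") = dims;
  return out;
}
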