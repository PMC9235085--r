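// Mesh primitives: marching-tetrahedra isosurface extraction on a 3D
// scalar field, and closest-point-on-triangle-mesh queries accelerated by
// a uniform grid. Index conventions match the R side: fields are arrays
// [slice, row, column]; extracted vertex coordinates are returned in
// fractional 0-based (slice, row, column) index space and converted to mm
// by the caller.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};

inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 add(const V3 &a, const V3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 scale(const V3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, 5.1.5).
V3 closest_on_triangle(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return add(a, scale(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return add(a, scale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scale(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scale(ab, v), scale(ac, w)));
}

} // namespace

// Marching tetrahedra over the 6-tet Kuhn decomposition of each grid cube.
// `field` must already be padded by the caller so that the boundary is
// strictly below `level` (closed surfaces). Inside = value >= level.
// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, double level) {
  IntegerVector dims = field.attr("dim");
  if (dims.size() != 3) stop("field must be a 3D array");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double *f = REAL(field);
  auto gidx = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)n1 * ((int64_t)j + (int64_t)n2 * k);
  };

  // six permutations of (0,1,2) for the Kuhn decomposition
  const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                           {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz; // in (i1,i2,i3) index coords
  std::vector<int> tri;           // 0-based vertex ids, triples

  const int64_t ntot = (int64_t)n1 * n2 * n3;

  auto edge_vert = [&](int64_t ga, int64_t gb, double fa, double fb,
                       const int pa[3], const int pb[3]) -> int {
    int64_t lo = ga < gb ? ga : gb, hi = ga < gb ? gb : ga;
    uint64_t key = (uint64_t)lo * (uint64_t)ntot + (uint64_t)hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    // interpolate in index space (i1, i2, i3)
    double p1 = pa[0] + t * (pb[0] - pa[0]);
    double p2 = pa[1] + t * (pb[1] - pa[1]);
    double p3 = pa[2] + t * (pb[2] - pa[2]);
    int id = (int)vx.size();
    vx.push_back(p1); vy.push_back(p2); vz.push_back(p3);
    edge_vertex.emplace(key, id);
    return id;
  };

  int tv[4][3]; // tet vertex offsets
  int64_t tg[4];
  double tf[4];
  int base[3];

  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        base[0] = i; base[1] = j; base[2] = k;
        for (int t = 0; t < 6; ++t) {
          // build tet: v0=origin, v1=v0+e_p0, v2=v1+e_p1, v3=(1,1,1)
          for (int a = 0; a < 3; ++a) tv[0][a] = base[a];
          for (int a = 0; a < 3; ++a) tv[1][a] = tv[0][a];
          tv[1][perms[t][0]] += 1;
          for (int a = 0; a < 3; ++a) tv[2][a] = tv[1][a];
          tv[2][perms[t][1]] += 1;
          tv[3][0] = i + 1; tv[3][1] = j + 1; tv[3][2] = k + 1;
          int nin = 0;
          int in_id[4], out_id[4], nin_i = 0, nout_i = 0;
          for (int a = 0; a < 4; ++a) {
            tg[a] = gidx(tv[a][0], tv[a][1], tv[a][2]);
            tf[a] = f[tg[a]];
            if (tf[a] >= level) { in_id[nin_i++] = a; ++nin; }
            else out_id[nout_i++] = a;
          }
          if (nin == 0 || nin == 4) continue;

          auto emit = [&](int a, int b, int c) {
            // orientation: normal should point inside -> outside
            V3 pa = {vx[a], vy[a], vz[a]};
            V3 pb = {vx[b], vy[b], vz[b]};
            V3 pc = {vx[c], vy[c], vz[c]};
            V3 nrm = cross(sub(pb, pa), sub(pc, pa));
            V3 cin = {0, 0, 0}, cout = {0, 0, 0};
            for (int q = 0; q < nin_i; ++q) {
              cin.x += tv[in_id[q]][0]; cin.y += tv[in_id[q]][1]; cin.z += tv[in_id[q]][2];
            }
            for (int q = 0; q < nout_i; ++q) {
              cout.x += tv[out_id[q]][0]; cout.y += tv[out_id[q]][1]; cout.z += tv[out_id[q]][2];
            }
            cin = scale(cin, 1.0 / nin_i); cout = scale(cout, 1.0 / nout_i);
            V3 ref = sub(cout, cin);
            if (dot(nrm, ref) < 0) { int tmp = b; b = c; c = tmp; }
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          };

          if (nin == 1) {
            int a = in_id[0];
            int e0 = edge_vert(tg[a], tg[out_id[0]], tf[a], tf[out_id[0]], tv[a], tv[out_id[0]]);
            int e1 = edge_vert(tg[a], tg[out_id[1]], tf[a], tf[out_id[1]], tv[a], tv[out_id[1]]);
            int e2 = edge_vert(tg[a], tg[out_id[2]], tf[a], tf[out_id[2]], tv[a], tv[out_id[2]]);
            if (e0 != e1 && e1 != e2 && e0 != e2) emit(e0, e1, e2);
          } else if (nin == 3) {
            int a = out_id[0];
            int e0 = edge_vert(tg[in_id[0]], tg[a], tf[in_id[0]], tf[a], tv[in_id[0]], tv[a]);
            int e1 = edge_vert(tg[in_id[1]], tg[a], tf[in_id[1]], tf[a], tv[in_id[1]], tv[a]);
            int e2 = edge_vert(tg[in_id[2]], tg[a], tf[in_id[2]], tf[a], tv[in_id[2]], tv[a]);
            if (e0 != e1 && e1 != e2 && e0 != e2) emit(e0, e1, e2);
          } else { // nin == 2: quad split into two triangles
            int a = in_id[0], b = in_id[1], c = out_id[0], d = out_id[1];
            int e_ac = edge_vert(tg[a], tg[c], tf[a], tf[c], tv[a], tv[c]);
            int e_ad = edge_vert(tg[a], tg[d], tf[a], tf[d], tv[a], tv[d]);
            int e_bd = edge_vert(tg[b], tg[d], tf[b], tf[d], tv[b], tv[d]);
            int e_bc = edge_vert(tg[b], tg[c], tf[b], tf[c], tv[b], tv[c]);
            if (e_ac != e_ad && e_ad != e_bd && e_ac != e_bd)
              emit(e_ac, e_ad, e_bd);
            if (e_ac != e_bd && e_bd != e_bc && e_ac != e_bc)
              emit(e_ac, e_bd, e_bc);
          }
        }
      }

  int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int a = 0; a < nv; ++a) {
    verts(a, 0) = vx[a]; verts(a, 1) = vy[a]; verts(a, 2) = vz[a];
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int a = 0; a < nt; ++a) {
    tris(a, 0) = tri[3 * a] + 1; // 1-based for R
    tris(a, 1) = tri[3 * a + 1] + 1;
    tris(a, 2) = tri[3 * a + 2] + 1;
  }
  return List::create(Named("vertices") = verts, Named("triangles") = tris);
}

// Closest point on a triangle mesh for each query point.
// Returns distances, closest points, and the triangle index hit.
// [[Rcpp::export(name = ".closest_point_mesh")]]
List closest_point_mesh(NumericMatrix query, NumericMatrix verts,
                        IntegerMatrix tris) {
  const int nq = query.nrow(), nt = tris.nrow();
  if (nt == 0) stop("mesh has no triangles");

  // mesh bbox
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int v = 0; v < verts.nrow(); ++v)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], verts(v, a));
      hi[a] = std::max(hi[a], verts(v, a));
    }
  double ext[3];
  for (int a = 0; a < 3; ++a) ext[a] = std::max(hi[a] - lo[a], 1e-9);

  // average triangle bbox extent -> cell size; grid capped at 64^3
  double avg_ext = 0;
  for (int t = 0; t < nt; ++t) {
    double tmin[3] = {R_PosInf, R_PosInf, R_PosInf};
    double tmax[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int s = 0; s < 3; ++s) {
      int v = tris(t, s) - 1;
      for (int a = 0; a < 3; ++a) {
        tmin[a] = std::min(tmin[a], verts(v, a));
        tmax[a] = std::max(tmax[a], verts(v, a));
      }
    }
    avg_ext += std::max({tmax[0] - tmin[0], tmax[1] - tmin[1], tmax[2] - tmin[2]});
  }
  avg_ext /= nt;
  double cell = std::max(avg_ext, std::max({ext[0], ext[1], ext[2]}) / 64.0);
  int dims[3];
  for (int a = 0; a < 3; ++a)
    dims[a] = std::max(1, std::min(64, (int)std::floor(ext[a] / cell) + 1));
  double csz[3];
  for (int a = 0; a < 3; ++a) csz[a] = ext[a] / dims[a];
  double min_csz = std::min({csz[0], csz[1], csz[2]});

  auto cell_of = [&](double x, int a) {
    int c = (int)std::floor((x - lo[a]) / csz[a]);
    return std::max(0, std::min(dims[a] - 1, c));
  };
  std::vector<std::vector<int>> buckets((size_t)dims[0] * dims[1] * dims[2]);
  auto bidx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)dims[0] * ((size_t)j + (size_t)dims[1] * k);
  };
  for (int t = 0; t < nt; ++t) {
    int cmin[3], cmax[3];
    for (int a = 0; a < 3; ++a) { cmin[a] = dims[a]; cmax[a] = -1; }
    for (int s = 0; s < 3; ++s) {
      int v = tris(t, s) - 1;
      for (int a = 0; a < 3; ++a) {
        int c = cell_of(verts(v, a), a);
        cmin[a] = std::min(cmin[a], c);
        cmax[a] = std::max(cmax[a], c);
      }
    }
    for (int k = cmin[2]; k <= cmax[2]; ++k)
      for (int j = cmin[1]; j <= cmax[1]; ++j)
        for (int i = cmin[0]; i <= cmax[0]; ++i)
          buckets[bidx(i, j, k)].push_back(t);
  }

  NumericVector dist(nq);
  NumericMatrix closest(nq, 3);
  IntegerVector tri_hit(nq);
  int maxdim = std::max({dims[0], dims[1], dims[2]});

  for (int q = 0; q < nq; ++q) {
    V3 p = {query(q, 0), query(q, 1), query(q, 2)};
    int ci = cell_of(p.x, 0), cj = cell_of(p.y, 1), ck = cell_of(p.z, 2);
    double best = R_PosInf;
    V3 bestp = {0, 0, 0};
    int bestt = -1;
    for (int r = 0; r <= maxdim; ++r) {
      if (bestt >= 0 && (double)(r - 1) * min_csz > std::sqrt(best)) break;
      bool any_cell = false;
      for (int k = ck - r; k <= ck + r; ++k) {
        if (k < 0 || k >= dims[2]) continue;
        for (int j = cj - r; j <= cj + r; ++j) {
          if (j < 0 || j >= dims[1]) continue;
          for (int i = ci - r; i <= ci + r; ++i) {
            if (i < 0 || i >= dims[0]) continue;
            // only the shell of the ring
            if (std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)}) != r)
              continue;
            any_cell = true;
            const std::vector<int> &bl = buckets[bidx(i, j, k)];
            for (int t : bl) {
              V3 a = {verts(tris(t, 0) - 1, 0), verts(tris(t, 0) - 1, 1), verts(tris(t, 0) - 1, 2)};
              V3 b = {verts(tris(t, 1) - 1, 0), verts(tris(t, 1) - 1, 1), verts(tris(t, 1) - 1, 2)};
              V3 c = {verts(tris(t, 2) - 1, 0), verts(tris(t, 2) - 1, 1), verts(tris(t, 2) - 1, 2)};
              V3 cp = closest_on_triangle(p, a, b, c);
              V3 d = sub(p, cp);
              double d2 = dot(d, d);
              if (d2 < best) { best = d2; bestp = cp; bestt = t; }
            }
          }
        }
      }
      if (!any_cell && r > maxdim) break;
    }
    dist[q] = std::sqrt(best);
    closest(q, 0) = bestp.x; closest(q, 1) = bestp.y; closest(q, 2) = bestp.z;
    tri_hit[q] = bestt + 1;
  }
  return List::create(Named("distance") = dist, Named("closest") = closest,
                      Named("triangle") = tri_hit);
}
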