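#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a[0] - b[0], a[1] - b[1], a[2] - b[2]}; }
static Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a[1] * b[2] - a[2] * b[1], a[2] * b[0] - a[0] * b[2], a[0] * b[1] - a[1] * b[0]};
}
static double vdot(const Vec3 &a, const Vec3 &b) { return a[0] * b[0] + a[1] * b[1] + a[2] * b[2]; }
static double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 normal;    // outward
  double offset;  // normal . vertex
  bool alive;
};

static Face make_face(int a, int b, int c, const std::vector<Vec3> &pts, const Vec3 &interior) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  f.normal = vcross(vsub(pts[b], pts[a]), vsub(pts[c], pts[a]));
  f.offset = vdot(f.normal, pts[a]);
  // orient outward (interior point on the negative side)
  if (vdot(f.normal, interior) > f.offset) {
    std::swap(f.b, f.c);
    f.normal = {-f.normal[0], -f.normal[1], -f.normal[2]};
    f.offset = -f.offset;
  }
  f.alive = true;
  return f;
}

// Volume of the convex hull of a 3D point set (incremental construction).
// Returns 0 for degenerate (coplanar or fewer than 4 distinct) inputs.
// [[Rcpp::export(name = ".cpp_convhull_volume")]]
double cpp_convhull_volume(NumericMatrix points) {
  const int n = points.nrow();
  if (n < 4) return 0.0;
  std::vector<Vec3> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {points(i, 0), points(i, 1), points(i, 2)};

  // characteristic scale for tolerances
  Vec3 lo = pts[0], hi = pts[0];
  for (const auto &p : pts)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], p[k]);
      hi[k] = std::max(hi[k], p[k]);
    }
  double diag = vnorm(vsub(hi, lo));
  if (diag <= 0) return 0.0;
  double eps = 1e-9 * diag * diag;  // offsets scale with area

  // initial tetrahedron: extreme point pair, then max-area, then max-volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n; ++i)
    if (pts[i][0] < pts[i0][0]) i0 = i;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vsub(pts[i], pts[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 1e-12 * diag) return 0.0;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vcross(vsub(pts[i1], pts[i0]), vsub(pts[i], pts[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= 1e-12 * diag * diag) return 0.0;
  Vec3 nrm = vcross(vsub(pts[i1], pts[i0]), vsub(pts[i2], pts[i0]));
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(vdot(nrm, vsub(pts[i], pts[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= 1e-12 * diag * diag * diag) return 0.0;  // coplanar cloud

  Vec3 interior = {0, 0, 0};
  for (int k : {i0, i1, i2, i3})
    for (int d = 0; d < 3; ++d) interior[d] += pts[k][d] / 4.0;

  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, pts, interior));
  faces.push_back(make_face(i0, i1, i3, pts, interior));
  faces.push_back(make_face(i0, i2, i3, pts, interior));
  faces.push_back(make_face(i1, i2, i3, pts, interior));

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && vdot(faces[f].normal, pts[p]) > faces[f].offset + eps)
        visible.push_back((int)f);
    if (visible.empty()) continue;
    // horizon = undirected edges of visible faces seen exactly once
    std::map<std::pair<int, int>, int> edge_count;
    for (int f : visible) {
      const Face &fa = faces[f];
      int vs[3] = {fa.a, fa.b, fa.c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        if (u > v) std::swap(u, v);
        edge_count[{u, v}]++;
      }
      faces[f].alive = false;
    }
    for (const auto &ec : edge_count)
      if (ec.second == 1)
        faces.push_back(make_face(ec.first.first, ec.first.second, p, pts, interior));
  }

  double vol = 0.0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    Vec3 a = vsub(pts[f.a], interior), b = vsub(pts[f.b], interior), c = vsub(pts[f.c], interior);
    vol += vdot(a, vcross(b, c)) / 6.0;
  }
  return std::fabs(vol);
}

// Isosurface area and enclosed volume by marching tetrahedra on the
// Freudenthal 6-tetrahedron decomposition of each lattice cell. Vertex
// coordinates are in voxel units; multiply area by spacing^2 and volume by
// spacing^3 for physical units. Triangles are oriented outward (away from
// the above-level region) so the divergence theorem gives the enclosed
// volume. Field values outside the array are not visited (pad in the
// caller if the surface may touch the border).
// [[Rcpp::export(name = ".cpp_isosurface_measure")]]
NumericVector cpp_isosurface_measure(NumericVector field, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int corner[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int tets[6][4] = {{0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}};
  double area = 0.0;
  double vol6 = 0.0;  // 6 x signed enclosed volume
  double fv[8];
  Vec3 pv[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        for (int c = 0; c < 8; ++c) {
          int xx = x + corner[c][0], yy = y + corner[c][1], zz = z + corner[c][2];
          fv[c] = field[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          pv[c] = {(double)xx, (double)yy, (double)zz};
        }
        for (int t = 0; t < 6; ++t) {
          int above[4], below[4];
          int na = 0, nb = 0;
          for (int k = 0; k < 4; ++k) {
            int v = tets[t][k];
            if (fv[v] > level) above[na++] = v; else below[nb++] = v;
          }
          if (na == 0 || na == 4) continue;
          auto interp = [&](int u, int v) -> Vec3 {
            double tt = (level - fv[u]) / (fv[v] - fv[u]);
            return {pv[u][0] + tt * (pv[v][0] - pv[u][0]),
                    pv[u][1] + tt * (pv[v][1] - pv[u][1]),
                    pv[u][2] + tt * (pv[v][2] - pv[u][2])};
          };
          // add a triangle oriented so its normal points away from the
          // above-level (interior) side; accumulate area and signed volume
          auto addTri = [&](Vec3 p1, Vec3 p2, Vec3 p3, const Vec3 &inside) {
            Vec3 nrm = vcross(vsub(p2, p1), vsub(p3, p1));
            if (vdot(nrm, vsub(inside, p1)) > 0) {
              std::swap(p2, p3);
              nrm = {-nrm[0], -nrm[1], -nrm[2]};
            }
            area += 0.5 * vnorm(nrm);
            vol6 += vdot(p1, vcross(p2, p3));
          };
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            const int *others = (na == 1) ? below : above;
            Vec3 p1 = interp(apex, others[0]);
            Vec3 p2 = interp(apex, others[1]);
            Vec3 p3 = interp(apex, others[2]);
            addTri(p1, p2, p3, pv[(na == 1) ? above[0] : above[0]]);
          } else {  // 2-2: quad split into two triangles
            Vec3 q1 = interp(above[0], below[0]);
            Vec3 q2 = interp(above[0], below[1]);
            Vec3 q3 = interp(above[1], below[1]);
            Vec3 q4 = interp(above[1], below[0]);
            addTri(q1, q2, q3, pv[above[0]]);
            addTri(q1, q3, q4, pv[above[0]]);
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}

// Which query points lie inside (or on) the convex hull of `points`.
// Rebuilds the hull, then tests each query against all face planes.
// [[Rcpp::export(name = ".cpp_convhull_contains")]]
LogicalVector cpp_convhull_contains(NumericMatrix points, NumericMatrix queries) {
  const int n = points.nrow();
  const int m = queries.nrow();
  LogicalVector out(m, false);
  if (n < 4) return out;
  std::vector<Vec3> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {points(i, 0), points(i, 1), points(i, 2)};
  Vec3 lo = pts[0], hi = pts[0];
  for (const auto &p : pts)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], p[k]);
      hi[k] = std::max(hi[k], p[k]);
    }
  double diag = vnorm(vsub(hi, lo));
  if (diag <= 0) return out;
  double eps = 1e-9 * diag * diag;

  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n; ++i)
    if (pts[i][0] < pts[i0][0]) i0 = i;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vsub(pts[i], pts[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 1e-12 * diag) return out;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vcross(vsub(pts[i1], pts[i0]), vsub(pts[i], pts[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= 1e-12 * diag * diag) return out;
  Vec3 nrm = vcross(vsub(pts[i1], pts[i0]), vsub(pts[i2], pts[i0]));
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(vdot(nrm, vsub(pts[i], pts[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= 1e-12 * diag * diag * diag) return out;

  Vec3 interior = {0, 0, 0};
  for (int k : {i0, i1, i2, i3})
    for (int d = 0; d < 3; ++d) interior[d] += pts[k][d] / 4.0;
  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, pts, interior));
  faces.push_back(make_face(i0, i1, i3, pts, interior));
  faces.push_back(make_face(i0, i2, i3, pts, interior));
  faces.push_back(make_face(i1, i2, i3, pts, interior));
  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && vdot(faces[f].normal, pts[p]) > faces[f].offset + eps)
        visible.push_back((int)f);
    if (visible.empty()) continue;
    std::map<std::pair<int, int>, int> edge_count;
    for (int f : visible) {
      const Face &fa = faces[f];
      int vs[3] = {fa.a, fa.b, fa.c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        if (u > v) std::swap(u, v);
        edge_count[{u, v}]++;
      }
      faces[f].alive = false;
    }
    for (const auto &ec : edge_count)
      if (ec.second == 1)
        faces.push_back(make_face(ec.first.first, ec.first.second, p, pts, interior));
  }
  std::vector<Face> live;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    // normalize plane for a scale-free containment tolerance
    Face g = f;
    double nn = vnorm(g.normal);
    if (nn > 0) {
      for (int k = 0; k < 3; ++k) g.normal[k] /= nn;
      g.offset /= nn;
    }
    live.push_back(g);
  }
  double tol = 1e-7 * diag;
  for (int q = 0; q < m; ++q) {
    Vec3 p = {queries(q, 0), queries(q, 1), queries(q, 2)};
    bool in = true;
    for (const Face &f : live)
      if (vdot(f.normal, p) > f.offset + tol) { in = false; break; }
    out[q] = in;
  }
  return out;
}
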