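#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Incremental 3D convex hull; returns the 1-based indices of the input
// points that are vertices of the hull. Points within eps (relative to the
// bounding-box diagonal) of a face plane are treated as on the plane and do
// not count as vertices, matching the "strict vertex" membership the
// visibility operator needs.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;     // vertex indices
  Vec3 n;          // outward normal (unit)
  double d;        // plane offset: dot(n, p) = d
  bool alive;
};

inline Face make_face(int a, int b, int c, const std::vector<Vec3> &P,
                      const Vec3 &inside) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  Vec3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  double ln = norm(n);
  if (ln > 0) { n.x /= ln; n.y /= ln; n.z /= ln; }
  double d = dot(n, P[a]);
  if (dot(n, inside) > d) {  // flip so the interior is below the plane
    n.x = -n.x; n.y = -n.y; n.z = -n.z; d = -d;
    int t = f.b; f.b = f.c; f.c = t;
  }
  f.n = n; f.d = d; f.alive = true;
  return f;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector hull3d_vertices(Rcpp::NumericMatrix pts, double tol = 1e-9) {
  const int n = pts.nrow();
  std::vector<Vec3> P(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double v[3] = {P[i].x, P[i].y, P[i].z};
    for (int k = 0; k < 3; ++k) {
      if (v[k] < lo[k]) lo[k] = v[k];
      if (v[k] > hi[k]) hi[k] = v[k];
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) diag = 1.0;
  const double eps = tol * diag;

  if (n < 4) {
    Rcpp::IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }

  // initial simplex: two extreme points, then farthest from line, then plane
  int i0 = 0, i1 = 0;
  {
    double best = -1.0;
    for (int k = 0; k < 3; ++k) {
      int lo_i = 0, hi_i = 0;
      double c0 = (k == 0) ? P[0].x : (k == 1) ? P[0].y : P[0].z;
      double lov = c0, hiv = c0;
      for (int i = 0; i < n; ++i) {
        double v = (k == 0) ? P[i].x : (k == 1) ? P[i].y : P[i].z;
        if (v < lov) { lov = v; lo_i = i; }
        if (v > hiv) { hiv = v; hi_i = i; }
      }
      double sep = hiv - lov;
      if (sep > best) { best = sep; i0 = lo_i; i1 = hi_i; }
    }
    if (best <= eps) return Rcpp::IntegerVector(0);  // all coincident
  }
  int i2 = -1;
  {
    double best = -1.0;
    Vec3 u = sub(P[i1], P[i0]);
    for (int i = 0; i < n; ++i) {
      double d = norm(cross(u, sub(P[i], P[i0]))) / norm(u);
      if (d > best) { best = d; i2 = i; }
    }
    if (best <= eps) return Rcpp::IntegerVector(0);  // collinear: degenerate
  }
  int i3 = -1;
  {
    Vec3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
    double ln = norm(nrm);
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot(nrm, sub(P[i], P[i0]))) / ln;
      if (d > best) { best = d; i3 = i; }
    }
    Vec3 nrm2 = nrm;
    double d3 = std::fabs(dot(nrm2, sub(P[i3], P[i0]))) / ln;
    if (d3 <= eps) return Rcpp::IntegerVector(0);  // coplanar: degenerate
  }

  Vec3 inside = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                 (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                 (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.reserve(6 * (size_t)n);
  faces.push_back(make_face(i0, i1, i2, P, inside));
  faces.push_back(make_face(i0, i1, i3, P, inside));
  faces.push_back(make_face(i0, i2, i3, P, inside));
  faces.push_back(make_face(i1, i2, i3, P, inside));

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    // collect faces visible from point i
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (dot(faces[f].n, P[i]) - faces[f].d > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // inside (or on) the current hull
    // horizon = edges of visible faces shared with a hidden face
    // count edge occurrences among visible faces
    std::vector<std::pair<int64_t, std::pair<int,int> > > edges;
    edges.reserve(vis.size() * 3);
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face &f = faces[vis[k]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        int u = e[j][0], v = e[j][1];
        int a = u < v ? u : v, b = u < v ? v : u;
        edges.push_back({(int64_t)a * n + b, {u, v}});
      }
    }
    for (size_t k = 0; k < vis.size(); ++k) faces[vis[k]].alive = false;
    for (size_t k = 0; k < edges.size(); ++k) {
      int cnt = 0;
      for (size_t j = 0; j < edges.size(); ++j)
        if (edges[j].first == edges[k].first) ++cnt;
      if (cnt == 1) {  // horizon edge: build a new face to point i
        faces.push_back(make_face(edges[k].second.first,
                                  edges[k].second.second, i, P, inside));
      }
    }
  }

  std::vector<char> vert(n, 0);
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    vert[faces[f].a] = vert[faces[f].b] = vert[faces[f].c] = 1;
  }
  std::vector<int> out;
  for (int i = 0; i < n; ++i) if (vert[i]) out.push_back(i + 1);
  return Rcpp::wrap(out);
}

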