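// Incremental 3D convex hull, volume only. Returns -1 for degenerate
// (coplanar/collinear) input. O(n^2) per insertion worst case; intended
// for point sets up to a few thousand atoms.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

namespace {

typedef std::array<double, 3> P3;

inline P3 sub(const P3& a, const P3& b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
inline P3 crossp(const P3& a, const P3& b) {
  return {a[1] * b[2] - a[2] * b[1],
          a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
inline double dotp(const P3& a, const P3& b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

struct Facet { int a, b, c; P3 normal; double offset; };

Facet make_facet(int a, int b, int c, const std::vector<P3>& pts,
                 const P3& interior) {
  Facet f; f.a = a; f.b = b; f.c = c;
  f.normal = crossp(sub(pts[b], pts[a]), sub(pts[c], pts[a]));
  f.offset = dotp(f.normal, pts[a]);
  if (dotp(f.normal, interior) > f.offset) { // flip outward
    std::swap(f.b, f.c);
    f.normal = {-f.normal[0], -f.normal[1], -f.normal[2]};
    f.offset = -f.offset;
  }
  return f;
}

} // namespace

// [[Rcpp::export]]
double hull_volume_cpp(NumericMatrix points) {
  const int n = points.nrow();
  std::vector<P3> pts(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    pts[i] = {points(i, 0), points(i, 1), points(i, 2)};
    for (int d = 0; d < 3; ++d) scale = std::max(scale, std::fabs(pts[i][d]));
  }
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10 * scale * scale * scale;

  // initial tetrahedron: four points with non-zero signed volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    P3 d = sub(pts[i], pts[i0]);
    if (dotp(d, d) > 1e-20 * scale * scale) i1 = i;
  }
  if (i1 < 0) return -1.0;
  for (int i = 1; i < n && i2 < 0; ++i) {
    if (i == i1) continue;
    P3 c = crossp(sub(pts[i1], pts[i0]), sub(pts[i], pts[i0]));
    if (dotp(c, c) > 1e-20 * scale * scale * scale * scale) i2 = i;
  }
  if (i2 < 0) return -1.0;
  for (int i = 1; i < n && i3 < 0; ++i) {
    if (i == i1 || i == i2) continue;
    P3 c = crossp(sub(pts[i1], pts[i0]), sub(pts[i2], pts[i0]));
    if (std::fabs(dotp(c, sub(pts[i], pts[i0]))) > eps) i3 = i;
  }
  if (i3 < 0) return -1.0;

  P3 interior = {(pts[i0][0] + pts[i1][0] + pts[i2][0] + pts[i3][0]) / 4.0,
                 (pts[i0][1] + pts[i1][1] + pts[i2][1] + pts[i3][1]) / 4.0,
                 (pts[i0][2] + pts[i1][2] + pts[i2][2] + pts[i3][2]) / 4.0};

  std::vector<Facet> facets;
  facets.push_back(make_facet(i0, i1, i2, pts, interior));
  facets.push_back(make_facet(i0, i1, i3, pts, interior));
  facets.push_back(make_facet(i0, i2, i3, pts, interior));
  facets.push_back(make_facet(i1, i2, i3, pts, interior));

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<char> visible(facets.size(), 0);
    bool any = false;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (dotp(facets[f].normal, pts[p]) - facets[f].offset > eps) {
        visible[f] = 1; any = true;
      }
    }
    if (!any) continue;
    // horizon edges: edges of visible facets not shared with another
    // visible facet
    std::vector<std::pair<int, int> > edges;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!visible[f]) continue;
      int vs[3] = {facets[f].a, facets[f].b, facets[f].c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        if (u > v) std::swap(u, v);
        bool shared = false;
        for (size_t g = 0; g < facets.size() && !shared; ++g) {
          if (g == f || !visible[g]) continue;
          int ws[3] = {facets[g].a, facets[g].b, facets[g].c};
          for (int e2 = 0; e2 < 3; ++e2) {
            int u2 = ws[e2], v2 = ws[(e2 + 1) % 3];
            if (u2 > v2) std::swap(u2, v2);
            if (u2 == u && v2 == v) { shared = true; break; }
          }
        }
        if (!shared) edges.push_back(std::make_pair(u, v));
      }
    }
    std::vector<Facet> next;
    for (size_t f = 0; f < facets.size(); ++f)
      if (!visible[f]) next.push_back(facets[f]);
    for (size_t e = 0; e < edges.size(); ++e)
      next.push_back(make_facet(edges[e].first, edges[e].second, p, pts,
                                interior));
    facets.swap(next);
  }

  double vol = 0.0;
  for (size_t f = 0; f < facets.size(); ++f) {
    P3 a = sub(pts[facets[f].a], interior);
    P3 b = sub(pts[facets[f].b], interior);
    P3 c = sub(pts[facets[f].c], interior);
    vol += std::fabs(dotp(a, crossp(b, c))) / 6.0;
  }
  return vol;
}
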