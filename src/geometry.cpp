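// Fast polygon area queries for the tiling and biopsy-placement hot loops.
//
// Regions built by the R layer (Clipper output) are lists of rings with
// orientation encoding holes. For area queries we triangulate every ring
// once (ear clipping) and evaluate area(query ∩ region) as the signed sum
// over rings of area(query ∩ ring), each computed by Sutherland-Hodgman
// clipping against a convex window (an axis-aligned tile rectangle or a
// triangle). S-H with a convex clip window yields the correct net area
// even for non-convex subject polygons.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> vd;

static double shoelace(const vd &x, const vd &y) {
  const int n = x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    a += x[j] * y[i] - x[i] * y[j];
  }
  return 0.5 * a;
}

// clip polygon (x, y) by the half-plane left of the directed line a->b
static void clip_halfplane(vd &x, vd &y, double ax, double ay, double bx, double by) {
  const int n = x.size();
  vd ox, oy;
  ox.reserve(n + 4);
  oy.reserve(n + 4);
  const double ex = bx - ax, ey = by - ay;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const double sj = ex * (y[j] - ay) - ey * (x[j] - ax); // >= 0: inside
    const double si = ex * (y[i] - ay) - ey * (x[i] - ax);
    const bool inj = sj >= 0.0, ini = si >= 0.0;
    if (inj != ini) {
      const double t = sj / (sj - si);
      ox.push_back(x[j] + t * (x[i] - x[j]));
      oy.push_back(y[j] + t * (y[i] - y[j]));
    }
    if (ini) {
      ox.push_back(x[i]);
      oy.push_back(y[i]);
    }
  }
  x.swap(ox);
  y.swap(oy);
}

static double clip_area_rect(const vd &px, const vd &py,
                             double x0, double y0, double x1, double y1) {
  vd x(px), y(py);
  clip_halfplane(x, y, x0, y0, x1, y0); // bottom, keep y >= y0
  if (x.size() < 3) return 0.0;
  clip_halfplane(x, y, x1, y0, x1, y1); // right, keep x <= x1
  if (x.size() < 3) return 0.0;
  clip_halfplane(x, y, x1, y1, x0, y1); // top
  if (x.size() < 3) return 0.0;
  clip_halfplane(x, y, x0, y1, x0, y0); // left
  if (x.size() < 3) return 0.0;
  return shoelace(x, y);
}

// area of (subject polygon ∩ tile rectangle) for many tiles; the subject
// ring may be CW or CCW - the absolute clipped area is returned
// [[Rcpp::export]]
NumericVector cpp_rect_clip_areas(NumericVector tx, NumericVector ty, double size,
                                  NumericVector px, NumericVector py) {
  const int nt = tx.size();
  vd sx(px.begin(), px.end()), sy(py.begin(), py.end());
  if (shoelace(sx, sy) < 0) { // force CCW so clipped areas are positive
    std::reverse(sx.begin(), sx.end());
    std::reverse(sy.begin(), sy.end());
  }
  double bxmin = sx[0], bxmax = sx[0], bymin = sy[0], bymax = sy[0];
  for (size_t i = 1; i < sx.size(); ++i) {
    bxmin = std::min(bxmin, sx[i]); bxmax = std::max(bxmax, sx[i]);
    bymin = std::min(bymin, sy[i]); bymax = std::max(bymax, sy[i]);
  }
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) {
    const double x0 = tx[i], y0 = ty[i], x1 = tx[i] + size, y1 = ty[i] + size;
    if (x1 <= bxmin || x0 >= bxmax || y1 <= bymin || y0 >= bymax) {
      out[i] = 0.0;
      continue;
    }
    out[i] = clip_area_rect(sx, sy, x0, y0, x1, y1);
  }
  return out;
}

// ear-clipping triangulation of a simple CCW polygon; returns an n x 6
// matrix of triangle vertices (x1 y1 x2 y2 x3 y3)
// [[Rcpp::export]]
NumericMatrix cpp_triangulate(NumericVector x, NumericVector y) {
  vd px(x.begin(), x.end()), py(y.begin(), y.end());
  if (shoelace(px, py) < 0) {
    std::reverse(px.begin(), px.end());
    std::reverse(py.begin(), py.end());
  }
  int n = px.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<std::array<double, 6> > tris;
  const double eps = 1e-12;
  while ((int)idx.size() > 3) {
    const int m = idx.size();
    bool clipped = false;
    int flattest = -1;
    double flattest_cross = std::numeric_limits<double>::max();
    for (int i = 0; i < m; ++i) {
      const int ia = idx[(i + m - 1) % m], ib = idx[i], ic = idx[(i + 1) % m];
      const double ax = px[ia], ay = py[ia], bx = px[ib], by = py[ib],
                   cx = px[ic], cy = py[ic];
      const double cross = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      if (std::fabs(cross) < flattest_cross) {
        flattest_cross = std::fabs(cross);
        flattest = i;
      }
      if (cross <= eps) continue; // reflex or degenerate corner
      // ear test: no other polygon vertex strictly inside triangle abc
      bool ear = true;
      for (int k = 0; k < m; ++k) {
        const int iv = idx[k];
        if (iv == ia || iv == ib || iv == ic) continue;
        const double vx = px[iv], vy = py[iv];
        const double d1 = (bx - ax) * (vy - ay) - (by - ay) * (vx - ax);
        const double d2 = (cx - bx) * (vy - by) - (cy - by) * (vx - bx);
        const double d3 = (ax - cx) * (vy - cy) - (ay - cy) * (vx - cx);
        if (d1 > eps && d2 > eps && d3 > eps) { ear = false; break; }
      }
      if (!ear) continue;
      tris.push_back({ax, ay, bx, by, cx, cy});
      idx.erase(idx.begin() + i);
      clipped = true;
      break;
    }
    if (!clipped) {
      // numerically stuck: remove the flattest corner and continue
      idx.erase(idx.begin() + flattest);
    }
  }
  if (idx.size() == 3) {
    tris.push_back({px[idx[0]], py[idx[0]], px[idx[1]], py[idx[1]],
                    px[idx[2]], py[idx[2]]});
  }
  NumericMatrix out(tris.size(), 6);
  for (size_t i = 0; i < tris.size(); ++i) {
    for (int j = 0; j < 6; ++j) out(i, j) = tris[i][j];
  }
  return out;
}

// area(subject polygon ∩ triangulated region); `tris` has columns
// x1 y1 x2 y2 x3 y3 sign, sign being +1 for outer-ring triangles and -1
// for hole-ring triangles
// [[Rcpp::export]]
double cpp_region_poly_area(NumericMatrix tris, NumericVector px, NumericVector py) {
  vd sx(px.begin(), px.end()), sy(py.begin(), py.end());
  if (shoelace(sx, sy) < 0) {
    std::reverse(sx.begin(), sx.end());
    std::reverse(sy.begin(), sy.end());
  }
  double bxmin = sx[0], bxmax = sx[0], bymin = sy[0], bymax = sy[0];
  for (size_t i = 1; i < sx.size(); ++i) {
    bxmin = std::min(bxmin, sx[i]); bxmax = std::max(bxmax, sx[i]);
    bymin = std::min(bymin, sy[i]); bymax = std::max(bymax, sy[i]);
  }
  double total = 0.0;
  for (int t = 0; t < tris.nrow(); ++t) {
    const double x1 = tris(t, 0), y1 = tris(t, 1), x2 = tris(t, 2),
                 y2 = tris(t, 3), x3 = tris(t, 4), y3 = tris(t, 5);
    const double txmin = std::min(x1, std::min(x2, x3));
    const double txmax = std::max(x1, std::max(x2, x3));
    const double tymin = std::min(y1, std::min(y2, y3));
    const double tymax = std::max(y1, std::max(y2, y3));
    if (txmax <= bxmin || txmin >= bxmax || tymax <= bymin || tymin >= bymax) continue;
    vd cx(sx), cy(sy);
    clip_halfplane(cx, cy, x1, y1, x2, y2);
    if (cx.size() < 3) continue;
    clip_halfplane(cx, cy, x2, y2, x3, y3);
    if (cx.size() < 3) continue;
    clip_halfplane(cx, cy, x3, y3, x1, y1);
    if (cx.size() < 3) continue;
    total += tris(t, 6) * shoelace(cx, cy);
  }
  return total;
}

static bool seg_intersect_proper(double ax, double ay, double bx, double by,
                                 double cx, double cy, double dx, double dy) {
  const double d1 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  const double d2 = (bx - ax) * (dy - ay) - (by - ay) * (dx - ax);
  const double d3 = (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx);
  const double d4 = (dx - cx) * (by - cy) - (dy - cy) * (bx - cx);
  return ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0));
}

static bool point_in_poly(double x, double y, const vd &px, const vd &py) {
  const int n = px.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])) {
      inside = !inside;
    }
  }
  return inside;
}

// positive-area overlap test for two simple polygons: proper edge crossing
// or containment of one polygon's vertex in the other
// [[Rcpp::export]]
bool cpp_polys_overlap(NumericVector ax, NumericVector ay,
                       NumericVector bx, NumericVector by) {
  vd Ax(ax.begin(), ax.end()), Ay(ay.begin(), ay.end());
  vd Bx(bx.begin(), bx.end()), By(by.begin(), by.end());
  double axmin = Ax[0], axmax = Ax[0], aymin = Ay[0], aymax = Ay[0];
  for (size_t i = 1; i < Ax.size(); ++i) {
    axmin = std::min(axmin, Ax[i]); axmax = std::max(axmax, Ax[i]);
    aymin = std::min(aymin, Ay[i]); aymax = std::max(aymax, Ay[i]);
  }
  double bxmin = Bx[0], bxmax = Bx[0], bymin = By[0], bymax = By[0];
  for (size_t i = 1; i < Bx.size(); ++i) {
    bxmin = std::min(bxmin, Bx[i]); bxmax = std::max(bxmax, Bx[i]);
    bymin = std::min(bymin, By[i]); bymax = std::max(bymax, By[i]);
  }
  if (axmax <= bxmin || axmin >= bxmax || aymax <= bymin || aymin >= bymax) {
    return false;
  }
  const int na = Ax.size(), nb = Bx.size();
  for (int i = 0, j = na - 1; i < na; j = i++) {
    for (int k = 0, l = nb - 1; k < nb; l = k++) {
      if (seg_intersect_proper(Ax[j], Ay[j], Ax[i], Ay[i],
                               Bx[l], By[l], Bx[k], By[k])) {
        return true;
      }
    }
  }
  if (point_in_poly(Ax[0], Ay[0], Bx, By)) return true;
  if (point_in_poly(Bx[0], By[0], Ax, Ay)) return true;
  return false;
}
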