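#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pixel (r, c) [0-based] occupies the unit square [c, c+1] x [r, r+1] in (x, y),
// y increasing downwards. Contour corners therefore live on the integer lattice.

static inline bool fg(const LogicalMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return false;
  return m(r, c) == TRUE;
}

// Label connected components of a binary mask. connectivity = 4 or 8.
// Returns integer matrix, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int nnb = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  for (int c0 = 0; c0 < nc; ++c0) for (int r0 = 0; r0 < nr; ++r0) {
    if (!mask(r0, c0) || lab(r0, c0)) continue;
    ++next;
    stack.push_back(r0 * nc + c0);
    lab(r0, c0) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int r = p / nc, c = p % nc;
      for (int k = 0; k < nnb; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr >= 0 && cc >= 0 && rr < nr && cc < nc && mask(rr, cc) && !lab(rr, cc)) {
          lab(rr, cc) = next;
          stack.push_back(rr * nc + cc);
        }
      }
    }
  }
  return lab;
}

// Background pixels 4-connected to the image border. Unreached background = holes.
// [[Rcpp::export]]
LogicalMatrix cpp_border_background(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix vis(nr, nc);
  std::vector<int> stack;
  auto push = [&](int r, int c) {
    if (r >= 0 && c >= 0 && r < nr && c < nc && !mask(r, c) && !vis(r, c)) {
      vis(r, c) = TRUE;
      stack.push_back(r * nc + c);
    }
  };
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int r = p / nc, c = p % nc;
    push(r - 1, c); push(r + 1, c); push(r, c - 1); push(r, c + 1);
  }
  return vis;
}

// Crack-edge boundary trace of the foreground region, keeping foreground on the
// right of the walk (y-down frame).  Vertices are lattice corners, so the shoelace
// area of the returned polygon equals the foreground pixel count exactly for a
// simply connected region.  Starts at the top-left corner of the first foreground
// pixel in (row, col) scan order; closed polygon returned open (last != first).
// [[Rcpp::export]]
NumericMatrix cpp_trace_boundary(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int r0 = -1, c0 = -1;
  for (int r = 0; r < nr && r0 < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) { r0 = r; c0 = c; break; }
  if (r0 < 0) stop("no foreground pixels to trace");

  // direction codes: 0=E(+x), 1=S(+y), 2=W(-x), 3=N(-y)
  const int dx[4] = {1, 0, -1, 0};
  const int dy[4] = {0, 1, 0, -1};
  // edge from corner (x, y) in direction d is valid iff foreground lies on its
  // right and background on its left (y-down)
  auto valid = [&](int x, int y, int d) {
    switch (d) {
    case 0: return  fg(mask, y,     x)     && !fg(mask, y - 1, x);
    case 1: return  fg(mask, y,     x - 1) && !fg(mask, y,     x);
    case 2: return  fg(mask, y - 1, x - 1) && !fg(mask, y,     x - 1);
    default:return  fg(mask, y - 1, x)     && !fg(mask, y - 1, x - 1);
    }
  };

  int x = c0, y = r0, d = 0;
  if (!valid(x, y, d)) stop("boundary trace failed to initialise");
  std::vector<double> xs, ys;
  long guard = 8L * (long)nr * nc + 64;
  int xstart = x, ystart = y, dstart = d;
  do {
    xs.push_back(x); ys.push_back(y);
    x += dx[d]; y += dy[d];
    // prefer right turn, then straight, then left, then reverse
    int nd = -1;
    int order[4] = {(d + 1) % 4, d, (d + 3) % 4, (d + 2) % 4};
    for (int k = 0; k < 4; ++k) if (valid(x, y, order[k])) { nd = order[k]; break; }
    if (nd < 0) stop("boundary trace dead end");
    d = nd;
    if (--guard <= 0) stop("boundary trace did not terminate");
  } while (!(x == xstart && y == ystart && d == dstart));

  NumericMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}

// Shortest distance from each query point to a closed polyline (vertex matrix,
// implicit closing edge).
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline(const NumericMatrix& pts, const NumericMatrix& poly) {
  int n = pts.nrow(), m = poly.nrow();
  if (m < 2) stop("polyline needs at least 2 vertices");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      int k = (j + 1 == m) ? 0 : j + 1;
      double ax = poly(j, 0), ay = poly(j, 1);
      double bx = poly(k, 0), by = poly(k, 1);
      double vx = bx - ax, vy = by - ay;
      double L2 = vx * vx + vy * vy;
      double t = (L2 > 0.0) ? ((px - ax) * vx + (py - ay) * vy) / L2 : 0.0;
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      double ex = ax + t * vx - px, ey = ay + t * vy - py;
      double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Even-odd scanline fill of a polygon on a regular grid.  Cell (r, c) [1-based in
// R] has centre (x0 + (c - 0.5) * step, y0 + (r - 0.5) * step).
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygon(const NumericMatrix& poly, int nrow, int ncol,
                               double x0, double y0, double step) {
  LogicalMatrix out(nrow, ncol);
  int m = poly.nrow();
  if (m < 3) return out;
  std::vector<double> xs;
  for (int r = 0; r < nrow; ++r) {
    double yc = y0 + (r + 0.5) * step;
    xs.clear();
    for (int j = 0; j < m; ++j) {
      int k = (j + 1 == m) ? 0 : j + 1;
      double y1 = poly(j, 1), y2 = poly(k, 1);
      if ((y1 <= yc && yc < y2) || (y2 <= yc && yc < y1)) {
        double x1 = poly(j, 0), x2 = poly(k, 0);
        xs.push_back(x1 + (yc - y1) * (x2 - x1) / (y2 - y1));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int c1 = (int)std::ceil((xs[p] - x0) / step - 0.5);
      int c2 = (int)std::floor((xs[p + 1] - x0) / step - 0.5);
      if (c1 < 0) c1 = 0;
      if (c2 > ncol - 1) c2 = ncol - 1;
      for (int c = c1; c <= c2; ++c) out(r, c) = TRUE;
    }
  }
  return out;
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool seg_intersect(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross2(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross2(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross2(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross2(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  return false;
}

// Strict self-intersection test for a closed polygon (adjacent edges excluded).
// [[Rcpp::export]]
bool cpp_polygon_is_simple(const NumericMatrix& poly) {
  int m = poly.nrow();
  if (m < 3) return false;
  for (int i = 0; i < m; ++i) {
    int i2 = (i + 1) % m;
    for (int j = i + 2; j < m; ++j) {
      int j2 = (j + 1) % m;
      if (j2 == i) continue;  // edges sharing the closing vertex
      if (seg_intersect(poly(i, 0), poly(i, 1), poly(i2, 0), poly(i2, 1),
                        poly(j, 0), poly(j, 1), poly(j2, 0), poly(j2, 1)))
        return false;
    }
  }
  return true;
}
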