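#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rings are closed polygons given as flattened vertex arrays; ring_start /
// ring_len index into vx/vy (0-based).  The closing edge (last -> first
// vertex) is implicit.

static inline double seg_dist2(double px, double py,
                               double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

// Even-odd (ray casting) point-in-polygon over a set of rings taken together,
// so holes carved out of outer rings are handled without orientation logic.
static inline bool inside_rings(double px, double py,
                                const NumericVector& vx, const NumericVector& vy,
                                const IntegerVector& ring_start,
                                const IntegerVector& ring_len) {
  bool inside = false;
  for (int r = 0; r < ring_start.size(); r++) {
    int s = ring_start[r], n = ring_len[r];
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = vx[s + i], yi = vy[s + i];
      double xj = vx[s + j], yj = vy[s + j];
      if (((yi > py) != (yj > py)) &&
          (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
        inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_rings_cpp(NumericVector px, NumericVector py,
                                  NumericVector vx, NumericVector vy,
                                  IntegerVector ring_start, IntegerVector ring_len) {
  int np = px.size();
  LogicalVector out(np);
  for (int k = 0; k < np; k++)
    out[k] = inside_rings(px[k], py[k], vx, vy, ring_start, ring_len);
  return out;
}

// Signed Euclidean distance from each point to the boundary of the region
// bounded by the rings: negative inside, positive outside, zero on the edge.
// [[Rcpp::export]]
NumericVector signed_distance_cpp(NumericVector px, NumericVector py,
                                  NumericVector vx, NumericVector vy,
                                  IntegerVector ring_start, IntegerVector ring_len) {
  int np = px.size();
  NumericVector out(np);
  for (int k = 0; k < np; k++) {
    double best = R_PosInf;
    for (int r = 0; r < ring_start.size(); r++) {
      int s = ring_start[r], n = ring_len[r];
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double d2 = seg_dist2(px[k], py[k], vx[s + j], vy[s + j],
                              vx[s + i], vy[s + i]);
        if (d2 < best) best = d2;
      }
    }
    double d = std::sqrt(best);
    out[k] = inside_rings(px[k], py[k], vx, vy, ring_start, ring_len) ? -d : d;
  }
  return out;
}
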