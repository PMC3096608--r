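#include <Rcpp.h>
using namespace Rcpp;

// Closest point on a closed polygon boundary for each query point.
// nodes: n x 2 matrix, CCW, element e joins node e and node e+1 (cyclic).
// [[Rcpp::export]]
List cpp_closest_point(NumericVector px, NumericVector py,
                       NumericMatrix nodes) {
  const int np = px.size();
  const int n = nodes.nrow();
  NumericVector dist(np), tpar(np);
  IntegerVector elem(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf, bt = 0.0;
    int be = 0;
    const double x = px[i], y = py[i];
    for (int e = 0; e < n; ++e) {
      const int e2 = (e + 1 == n) ? 0 : e + 1;
      const double ax = nodes(e, 0), ay = nodes(e, 1);
      const double dx = nodes(e2, 0) - ax, dy = nodes(e2, 1) - ay;
      const double L2 = dx * dx + dy * dy;
      double t = ((x - ax) * dx + (y - ay) * dy) / L2;
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      const double qx = ax + t * dx - x, qy = ay + t * dy - y;
      const double d2 = qx * qx + qy * qy;
      if (d2 < best) { best = d2; be = e; bt = t; }
    }
    dist[i] = std::sqrt(best);
    elem[i] = be + 1;
    tpar[i] = bt;
  }
  return List::create(_["dist"] = dist, _["element"] = elem,
                      _["t"] = tpar);
}

// Even-odd (crossing number) point-in-polygon test.
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector px, NumericVector py,
                                   NumericMatrix nodes) {
  const int np = px.size();
  const int n = nodes.nrow();
  LogicalVector inside(np);
  for (int i = 0; i < np; ++i) {
    const double x = px[i], y = py[i];
    bool in = false;
    int j = n - 1;
    for (int k = 0; k < n; ++k) {
      const double xi = nodes(k, 0), yi = nodes(k, 1);
      const double xj = nodes(j, 0), yj = nodes(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        in = !in;
      j = k;
    }
    inside[i] = in;
  }
  return inside;
}

// Any proper intersection between non-adjacent elements of a closed
// polygon (simplicity test).
// [[Rcpp::export]]
bool cpp_polygon_is_simple(NumericMatrix nodes) {
  const int n = nodes.nrow();
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1 == n) ? 0 : i + 1;
    const double a1x = nodes(i, 0), a1y = nodes(i, 1);
    const double d1x = nodes(i2, 0) - a1x, d1y = nodes(i2, 1) - a1y;
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through the wrap
      const int j2 = (j + 1 == n) ? 0 : j + 1;
      const double b1x = nodes(j, 0), b1y = nodes(j, 1);
      const double d2x = nodes(j2, 0) - b1x, d2y = nodes(j2, 1) - b1y;
      const double denom = d1x * d2y - d1y * d2x;
      if (std::abs(denom) < 1e-300) continue;
      const double rx = b1x - a1x, ry = b1y - a1y;
      const double t = (rx * d2y - ry * d2x) / denom;
      const double u = (rx * d1y - ry * d1x) / denom;
      if (t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0) return false;
    }
  }
  return true;
}
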