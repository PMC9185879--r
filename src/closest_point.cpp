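#include <Rcpp.h>
using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection 5.1.5)
static inline void closestPtTri(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// For each query point, the closest point on the triangle mesh (V, F),
// the distance, and the 1-based index of the nearest face.
// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericMatrix Q(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    double best = R_PosInf, bq[3] = {0, 0, 0};
    int bf = 0;
    for (int jf = 0; jf < nf; ++jf) {
      int ia = F(jf, 0) - 1, ib = F(jf, 1) - 1, ic = F(jf, 2) - 1;
      double a[3] = {vx[ia], vy[ia], vz[ia]};
      double b[3] = {vx[ib], vy[ib], vz[ib]};
      double c[3] = {vx[ic], vy[ic], vz[ic]};
      double q[3];
      closestPtTri(p, a, b, c, q);
      double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2];
        bf = jf + 1;
      }
    }
    Q(ip, 0) = bq[0]; Q(ip, 1) = bq[1]; Q(ip, 2) = bq[2];
    dist[ip] = std::sqrt(best);
    face[ip] = bf;
  }
  return List::create(_["points"] = Q, _["distance"] = dist,
                      _["face"] = face);
}
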