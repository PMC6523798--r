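#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Uniform sampling of equilateral closed k-gons in the fan-diagonal
// (action-angle) coordinates: the k-3 differences between neighbouring
// fan diagonals are drawn uniformly from [-1,1]; a draw is valid iff every
// fan triangle (d_{j-1}, d_j, 1) satisfies the triangle inequalities, with
// d_0 = d_{k-2} = 1 the two unit edges at vertex 0.  Valid diagonal
// sequences are completed with uniform dihedral angles about each diagonal.
// Rejection of invalid sequences preserves the uniform measure on the
// diagonal polytope.  All randomness comes from R's RNG.

// [[Rcpp::export]]
List cpp_sample_polygon(int k) {
  if (k < 3) stop("polygon needs at least 3 edges (k >= 3)");
  NumericMatrix V(k, 3);
  if (k == 3) {
    V(1, 0) = 1.0;
    V(2, 0) = 0.5;
    V(2, 1) = std::sqrt(3.0) / 2.0;
    return List::create(_["vertices"] = V, _["attempts"] = 1.0);
  }

  const int m = k - 1;           // d[0..k-2]; d[0] = d[k-2] = 1 are edges
  std::vector<double> d(m);
  d[0] = 1.0;
  d[m - 1] = 1.0;

  double attempts = 0.0;
  bool ok = false;
  while (!ok) {
    attempts += 1.0;
    if (attempts > 5e8) stop("polygon sampler failed to accept a draw");
    ok = true;
    double prev = 1.0;
    for (int j = 1; j <= k - 3; ++j) {
      double cur = prev + (2.0 * unif_rand() - 1.0);
      // triangle (d_{j-1}, d_j, 1): |d_j - d_{j-1}| <= 1 holds by
      // construction; need d_j >= 0 and d_j + d_{j-1} >= 1
      if (cur < 0.0 || cur + prev < 1.0) { ok = false; break; }
      d[j] = cur;
      prev = cur;
    }
    if (ok) {
      // closing triangle (d_{k-3}, 1, 1)
      double last = d[m - 2];
      if (std::fabs(1.0 - last) > 1.0) ok = false;
      // guard against a numerically degenerate fan apex distance
      if (ok) {
        for (int j = 1; j <= k - 3; ++j)
          if (d[j] < 1e-9) { ok = false; break; }
      }
    }
  }

  // Rebuild the polygon as a fan of triangles over vertex 0.
  V(0, 0) = 0.0; V(0, 1) = 0.0; V(0, 2) = 0.0;
  V(1, 0) = 1.0; V(1, 1) = 0.0; V(1, 2) = 0.0;
  for (int j = 1; j <= k - 2; ++j) {
    // place vertex j+1: |v0 v_{j+1}| = d[j], |v_j v_{j+1}| = 1
    double dm = d[j - 1], dj = d[j];
    double ux = V(j, 0) / dm, uy = V(j, 1) / dm, uz = V(j, 2) / dm;
    double t = (dm * dm + dj * dj - 1.0) / (2.0 * dm);
    double r2 = dj * dj - t * t;
    double r = r2 > 0.0 ? std::sqrt(r2) : 0.0;
    // orthonormal frame (e1, e2) perpendicular to u
    double hx, hy, hz;
    if (std::fabs(ux) <= 0.9) { hx = 1.0; hy = 0.0; hz = 0.0; }
    else                      { hx = 0.0; hy = 1.0; hz = 0.0; }
    double e1x = uy * hz - uz * hy;
    double e1y = uz * hx - ux * hz;
    double e1z = ux * hy - uy * hx;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = uy * e1z - uz * e1y;
    double e2y = uz * e1x - ux * e1z;
    double e2z = ux * e1y - uy * e1x;
    // dihedral angle about the diagonal (first triangle fixes the frame)
    double th = (j == 1) ? 0.0 : 2.0 * M_PI * unif_rand();
    double ct = std::cos(th), st = std::sin(th);
    V(j + 1, 0) = t * ux + r * (ct * e1x + st * e2x);
    V(j + 1, 1) = t * uy + r * (ct * e1y + st * e2y);
    V(j + 1, 2) = t * uz + r * (ct * e1z + st * e2z);
  }

  return List::create(_["vertices"] = V, _["attempts"] = attempts);
}
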