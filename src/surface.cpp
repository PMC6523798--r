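#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Near-minimal triangulated surface spanned on a closed polygonal loop.
//
// Construction: a fan of triangles from the loop centroid, refined by
// conforming edge-midpoint subdivision (interleaved with cheap smoothing
// so the refinement tracks the contracting surface) until every
// non-boundary edge is at most the target edge length, then relaxed by
// sweeps that move interior vertices only.  A sweep combines
// area-decreasing edge flips with over-relaxed Gauss-Seidel passes of the
// cotangent-Laplacian (Pinkall-Polthier style) vertex update; when a pass
// fails to decrease the total area it falls back to plain averaging and
// then to backtracking area-gradient descent, so the area trace is
// monotonically non-increasing.  The boundary vertices (the loop) never
// move.

static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static double total_area(const std::vector<double>& V,
                         const std::vector<int>& F) {
  double A = 0.0;
  size_t nf = F.size() / 3;
  for (size_t f = 0; f < nf; ++f) {
    const double* a = &V[3 * F[3 * f]];
    const double* b = &V[3 * F[3 * f + 1]];
    const double* c = &V[3 * F[3 * f + 2]];
    double e1[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double e2[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
    double n[3];
    vcross(e1, e2, n);
    A += 0.5 * std::sqrt(vdot(n, n));
  }
  return A;
}

// d(Area)/d(vertex) accumulated over all triangles; zero rows for fixed verts
static void area_gradient(const std::vector<double>& V,
                          const std::vector<int>& F, int nb,
                          std::vector<double>& G) {
  std::fill(G.begin(), G.end(), 0.0);
  size_t nf = F.size() / 3;
  for (size_t f = 0; f < nf; ++f) {
    int ia = F[3 * f], ib = F[3 * f + 1], ic = F[3 * f + 2];
    const double* a = &V[3 * ia];
    const double* b = &V[3 * ib];
    const double* c = &V[3 * ic];
    double e1[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double e2[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
    double n[3];
    vcross(e1, e2, n);
    double nn = std::sqrt(vdot(n, n));
    if (nn < 1e-14) continue;
    double nh[3] = { n[0] / nn, n[1] / nn, n[2] / nn };
    // dA/da = 0.5 * nh x (c - b), and cyclic
    double cb[3] = { c[0] - b[0], c[1] - b[1], c[2] - b[2] };
    double ac[3] = { a[0] - c[0], a[1] - c[1], a[2] - c[2] };
    double ba[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double g[3];
    if (ia >= nb) {
      vcross(nh, cb, g);
      G[3 * ia] += 0.5 * g[0]; G[3 * ia + 1] += 0.5 * g[1]; G[3 * ia + 2] += 0.5 * g[2];
    }
    if (ib >= nb) {
      vcross(nh, ac, g);
      G[3 * ib] += 0.5 * g[0]; G[3 * ib + 1] += 0.5 * g[1]; G[3 * ib + 2] += 0.5 * g[2];
    }
    if (ic >= nb) {
      vcross(nh, ba, g);
      G[3 * ic] += 0.5 * g[0]; G[3 * ic + 1] += 0.5 * g[1]; G[3 * ic + 2] += 0.5 * g[2];
    }
  }
}

// vertex -> incident triangle lists (all vertices), updated across flips
typedef std::vector<std::vector<int> > Incidence;

static void build_incidence(const std::vector<int>& F, int nv,
                            Incidence& inc) {
  inc.assign(nv, std::vector<int>());
  size_t nf = F.size() / 3;
  for (size_t f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) inc[F[3 * f + j]].push_back((int)f);
}

static inline bool tri_has(const std::vector<int>& F, int f, int v) {
  return F[3 * f] == v || F[3 * f + 1] == v || F[3 * f + 2] == v;
}

// the other triangle sharing edge (u,v) with f, or -1
static inline int edge_partner(const std::vector<int>& F,
                               const Incidence& inc, int u, int v, int f) {
  for (int t : inc[u])
    if (t != f && tri_has(F, t, v)) return t;
  return -1;
}

static inline void inc_remove(Incidence& inc, int v, int f) {
  auto& lst = inc[v];
  for (size_t i = 0; i < lst.size(); ++i)
    if (lst[i] == f) { lst[i] = lst.back(); lst.pop_back(); return; }
}

// One Gauss-Seidel cotangent-Laplacian pass over interior vertices.
static void laplace_sweep(std::vector<double>& V, const std::vector<int>& F,
                          int nb, const Incidence& inc, double omega) {
  int nv = (int)(V.size() / 3);
  for (int v = nb; v < nv; ++v) {
    double wsum = 0.0, acc[3] = { 0.0, 0.0, 0.0 };
    for (size_t s = 0; s < inc[v].size(); ++s) {
      int fid = inc[v][s];
      int i0 = F[3 * fid], i1 = F[3 * fid + 1], i2 = F[3 * fid + 2];
      // rotate so that i0 == v
      if (i1 == v) { int t = i0; i0 = i1; i1 = i2; i2 = t; }
      else if (i2 == v) { int t = i2; i2 = i1; i1 = i0; i0 = t; }
      const double* p = &V[3 * i0];
      const double* q = &V[3 * i1];
      const double* r = &V[3 * i2];
      // contribution of this triangle to edges (v,q) with cot at r and
      // (v,r) with cot at q
      double rq[3] = { q[0] - r[0], q[1] - r[1], q[2] - r[2] };
      double rp[3] = { p[0] - r[0], p[1] - r[1], p[2] - r[2] };
      double qp[3] = { p[0] - q[0], p[1] - q[1], p[2] - q[2] };
      double qr[3] = { -rq[0], -rq[1], -rq[2] };
      double cr[3], cq[3];
      vcross(rq, rp, cr);
      double cot_r = vdot(rq, rp) / std::max(std::sqrt(vdot(cr, cr)), 1e-14);
      vcross(qp, qr, cq);
      double cot_q = vdot(qp, qr) / std::max(std::sqrt(vdot(cq, cq)), 1e-14);
      // clamp: keep the update a convex combination (robust to slivers)
      cot_r = std::max(cot_r, 0.0);
      cot_q = std::max(cot_q, 0.0);
      wsum += cot_r + cot_q;
      acc[0] += cot_r * q[0] + cot_q * r[0];
      acc[1] += cot_r * q[1] + cot_q * r[1];
      acc[2] += cot_r * q[2] + cot_q * r[2];
    }
    if (wsum > 1e-12) {
      // over-relaxed Gauss-Seidel update (omega = 1 is plain averaging)
      for (int d = 0; d < 3; ++d)
        V[3 * v + d] += omega * (acc[d] / wsum - V[3 * v + d]);
    }
  }
}

static inline double tri_area(const std::vector<double>& V, int a, int b,
                              int c) {
  const double* p = &V[3 * a];
  const double* q = &V[3 * b];
  const double* r = &V[3 * c];
  double e1[3] = { q[0] - p[0], q[1] - p[1], q[2] - p[2] };
  double e2[3] = { r[0] - p[0], r[1] - p[1], r[2] - p[2] };
  double n[3];
  vcross(e1, e2, n);
  return 0.5 * std::sqrt(vdot(n, n));
}

// One deterministic pass of area-decreasing edge flips.  For an interior
// edge (u,v) shared by (u,v,a) and (v,u,b), replacing it with (a,b) keeps
// the mesh an orientable disk with the same boundary; the flip is applied
// when it strictly lowers the summed area of the two triangles.  The
// incidence lists are updated in place.  Returns the total area decrease.
static double flip_pass(const std::vector<double>& V, std::vector<int>& F,
                        int nb, Incidence& inc, std::vector<char>& dirty) {
  size_t nf = F.size() / 3;
  dirty.assign(nf, 0);
  double gain = 0.0;
  for (size_t f = 0; f < nf; ++f) {
    if (dirty[f]) continue;
    for (int j = 0; j < 3; ++j) {
      int u = F[3 * f + j], v = F[3 * f + (j + 1) % 3];
      int a = F[3 * f + (j + 2) % 3];
      if (u < nb && v < nb) continue;  // never flip a boundary edge
      int f2 = edge_partner(F, inc, u, v, (int)f);
      if (f2 < 0 || dirty[f2]) continue;
      int b = -1;
      for (int t = 0; t < 3; ++t) {
        int w = F[3 * f2 + t];
        if (w != u && w != v) b = w;
      }
      if (b < 0 || a == b) continue;
      // keep the mesh simple: the new diagonal must not already exist
      if (edge_partner(F, inc, a, b, -1) >= 0) continue;
      double before = tri_area(V, u, v, a) + tri_area(V, v, u, b);
      double after = tri_area(V, u, b, a) + tri_area(V, v, a, b);
      if (after < before - 1e-14 && after < before * (1.0 - 1e-10)) {
        // orient the children consistently with the parents
        F[3 * f] = u; F[3 * f + 1] = b; F[3 * f + 2] = a;
        F[3 * f2] = v; F[3 * f2 + 1] = a; F[3 * f2 + 2] = b;
        inc_remove(inc, u, f2);
        inc_remove(inc, v, (int)f);
        inc[a].push_back(f2);
        inc[b].push_back((int)f);
        dirty[f] = dirty[f2] = 1;
        gain += before - after;
        break;
      }
    }
  }
  return gain;
}

// [[Rcpp::export]]
List cpp_span_surface(NumericMatrix loop, double target_edge, double tol,
                      int max_sweeps) {
  int nb = loop.nrow();
  if (nb < 3) stop("loop needs at least 3 vertices");
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < 3; ++j)
      if (!R_finite(loop(i, j))) stop("non-finite loop coordinates");

  std::vector<double> V(3 * (nb + 1));
  double cen[3] = { 0.0, 0.0, 0.0 };
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < 3; ++j) {
      V[3 * i + j] = loop(i, j);
      cen[j] += loop(i, j) / nb;
    }
  }
  V[3 * nb] = cen[0]; V[3 * nb + 1] = cen[1]; V[3 * nb + 2] = cen[2];

  std::vector<int> F;
  F.reserve(3 * nb);
  for (int i = 0; i < nb; ++i) {
    F.push_back(i);
    F.push_back((i + 1) % nb);
    F.push_back(nb);
  }

  double mean_edge = 0.0;
  for (int i = 0; i < nb; ++i) {
    const double* a = &V[3 * i];
    const double* b = &V[3 * ((i + 1) % nb)];
    double d[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    mean_edge += std::sqrt(vdot(d, d)) / nb;
  }
  double area_init = total_area(V, F);
  if (area_init < 1e-12 * mean_edge * mean_edge)
    stop("degenerate-surface: loop vertices are (numerically) collinear");

  // --- coarse-to-fine optimisation -------------------------------------
  // Each resolution level is optimised (vertex relaxation + edge flips)
  // before the mesh is refined further, so most of the work happens on
  // coarse meshes; the final mesh satisfies the target edge length.
  double target = target_edge > 0.0 ? target_edge : mean_edge;

  auto refine_once = [&]() -> bool {
    std::unordered_map<int64_t, int> mid;
    bool any = false;
    size_t nf = F.size() / 3;
    auto edge_key = [](int a, int b) {
      if (a > b) std::swap(a, b);
      return ((int64_t)a << 32) | (uint32_t)b;
    };
    auto midpoint = [&](int a, int b) -> int {
      if (a < nb && b < nb) return -1;  // never split boundary edges
      double d[3] = { V[3 * b] - V[3 * a], V[3 * b + 1] - V[3 * a + 1],
                      V[3 * b + 2] - V[3 * a + 2] };
      if (std::sqrt(vdot(d, d)) <= target * (1.0 + 1e-12)) return -1;
      int64_t key = edge_key(a, b);
      auto it = mid.find(key);
      if (it != mid.end()) return it->second;
      int idx = (int)(V.size() / 3);
      V.push_back(0.5 * (V[3 * a] + V[3 * b]));
      V.push_back(0.5 * (V[3 * a + 1] + V[3 * b + 1]));
      V.push_back(0.5 * (V[3 * a + 2] + V[3 * b + 2]));
      mid[key] = idx;
      any = true;
      return idx;
    };
    std::vector<int> NF;
    NF.reserve(F.size() * 2);
    for (size_t f = 0; f < nf; ++f) {
      int a = F[3 * f], b = F[3 * f + 1], c = F[3 * f + 2];
      int mab = midpoint(a, b), mbc = midpoint(b, c), mca = midpoint(c, a);
      int nsplit = (mab >= 0) + (mbc >= 0) + (mca >= 0);
      if (nsplit == 0) {
        NF.insert(NF.end(), { a, b, c });
      } else if (nsplit == 3) {
        NF.insert(NF.end(), { a, mab, mca, mab, b, mbc, mca, mbc, c,
                              mab, mbc, mca });
      } else {
        // rotate labels so the first edge (a,b) is split
        for (int r = 0; r < 3 && mab < 0; ++r) {
          int t = a; a = b; b = c; c = t;
          t = mab; mab = mbc; mbc = mca; mca = t;
        }
        if (nsplit == 1) {
          NF.insert(NF.end(), { a, mab, c, mab, b, c });
        } else {
          // two edges split; rotate once more if the split pair is (ab, ca)
          if (mbc < 0) {
            int t = c; c = b; b = a; a = t;        // (a,b,c) -> (c,a,b)
            t = mbc; mbc = mab; mab = mca; mca = t;
          }
          NF.insert(NF.end(), { a, mab, c, mab, b, mbc, mab, mbc, c });
        }
      }
    }
    F.swap(NF);
    return any;
  };

  double step = 0.25 * target;
  int sweeps_total = 0;
  double A = total_area(V, F);
  Incidence inc;
  std::vector<double> G, Vtry;
  std::vector<char> dirty;

  auto relax = [&](int budget, bool use_flips) {
    int nv = (int)(V.size() / 3);
    build_incidence(F, nv, inc);
    G.assign(V.size(), 0.0);
    step = 0.25 * target;
    int flip_idle = 0;
    A = total_area(V, F);
    for (int s = 0; s < budget; ++s, ++sweeps_total) {
      double A0 = A;
      // connectivity improvement: area-decreasing edge flips, iterated to
      // (near) exhaustion; once they stop paying they are retried only
      // every fourth sweep
      double gain = 0.0;
      if (use_flips && flip_idle == 0) {
        for (int fp = 0; fp < 8; ++fp) {
          double g = flip_pass(V, F, nb, inc, dirty);
          gain += g;
          if (g <= tol * A * 0.1) break;
        }
        // once flips stop paying, retry them only every fourth sweep
        if (gain <= tol * A) flip_idle = 3;
      } else if (flip_idle > 0) {
        --flip_idle;
      }
      if (gain > 0.0) A -= gain;
      // a few smoothing passes: over-relaxed first, plain averaging as
      // the monotone guard
      bool moved = false;
      for (int lp = 0; lp < 3; ++lp) {
        Vtry = V;
        laplace_sweep(Vtry, F, nb, inc, 1.7);
        double Al = total_area(Vtry, F);
        if (Al >= A) {
          Vtry = V;
          laplace_sweep(Vtry, F, nb, inc, 1.0);
          Al = total_area(Vtry, F);
        }
        if (Al < A) {
          V.swap(Vtry);
          A = Al;
          moved = true;
        } else break;
      }
      double A1 = A;
      if (!moved && gain <= 0.0) {
        // monotone fallback: gradient descent with backtracking
        area_gradient(V, F, nb, G);
        bool improved = false;
        for (int h = 0; h < 14; ++h) {
          Vtry = V;
          for (int v = nb; v < nv; ++v)
            for (int j = 0; j < 3; ++j)
              Vtry[3 * v + j] -= step * G[3 * v + j];
          A1 = total_area(Vtry, F);
          if (A1 < A) {
            V.swap(Vtry);
            A = A1;
            step *= 1.3;
            improved = true;
            break;
          }
          step *= 0.5;
        }
        if (!improved) break;  // numerically converged
      }
      if ((A0 - A) / A0 < tol) break;
    }
  };

  // Coarse-to-fine: each level is smoothed (no flips) until its area
  // settles before edges are split, so refinement tracks the contracted
  // surface instead of the inflated initial fan; the full relaxation with
  // edge flips runs at the final resolution.
  relax(std::min(10, max_sweeps), false);
  // bounded refinement: smoothing can re-stretch the odd edge past the
  // target, so the alternation must not be allowed to cycle forever
  for (int pass = 0; pass < 12 && refine_once(); ++pass)
    relax(std::min(10, max_sweeps), false);
  relax(max_sweeps, true);

  int nv = (int)(V.size() / 3);
  size_t nf = F.size() / 3;
  int sweeps = sweeps_total;

  NumericMatrix Vout(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int j = 0; j < 3; ++j) Vout(v, j) = V[3 * v + j];
  IntegerMatrix Fout((int)nf, 3);
  for (size_t f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) Fout((int)f, j) = F[3 * f + j] + 1;

  return List::create(_["vertices"] = Vout, _["triangles"] = Fout,
                      _["n_boundary"] = nb, _["area"] = A,
                      _["area_initial"] = area_init,
                      _["sweeps"] = sweeps, _["mean_edge"] = mean_edge);
}

// ---------------------------------------------------------------------------
// Transversal piercings of a polyline tail through the open surface interior.
// Signed by the orientation of the crossing w.r.t. the (consistent) triangle
// normals.  Hits within eps of the boundary curve or of the anchor vertex are
// excluded; near-degenerate hits (on a mesh edge/vertex, or at a tail vertex)
// trigger a deterministic retry with the whole tail shifted by a fixed tiny
// vector.

struct GridHash {
  double h;
  double org[3];
  std::unordered_map<int64_t, std::vector<int> > cells;
  int64_t key(int ix, int iy, int iz) const {
    return ((int64_t)(ix & 0x1FFFFF) << 42) | ((int64_t)(iy & 0x1FFFFF) << 21)
         | (int64_t)(iz & 0x1FFFFF);
  }
};

static double point_segment_dist2(const double* p, const double* a,
                                  const double* b) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double t = vdot(ap, ab) / std::max(vdot(ab, ab), 1e-300);
  t = std::min(1.0, std::max(0.0, t));
  double d[3] = { ap[0] - t * ab[0], ap[1] - t * ab[1], ap[2] - t * ab[2] };
  return vdot(d, d);
}

// [[Rcpp::export]]
List cpp_count_piercings(NumericMatrix Vm, IntegerMatrix Fm, int nb,
                         NumericMatrix tail, NumericVector anchor,
                         double mean_edge) {
  int nv = Vm.nrow(), nf = Fm.nrow(), nt = tail.nrow();
  if (nt < 1) stop("empty tail");
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j)
      if (!R_finite(tail(i, j))) stop("non-finite tail coordinates");

  std::vector<double> V(3 * nv);
  for (int v = 0; v < nv; ++v)
    for (int j = 0; j < 3; ++j) V[3 * v + j] = Vm(v, j);
  std::vector<int> F(3 * nf);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) F[3 * f + j] = Fm(f, j) - 1;

  const double eps_excl = 1e-9 * mean_edge;   // boundary / anchor exclusion
  const double eps_bary = 1e-11;              // degeneracy window
  const double pert = 1e-10 * mean_edge;      // deterministic tie-break shift

  // does a triangle touch the boundary curve?
  std::vector<char> touches(nf, 0);
  for (int f = 0; f < nf; ++f)
    touches[f] = (F[3 * f] < nb || F[3 * f + 1] < nb || F[3 * f + 2] < nb);

  // spatial hash over triangles
  GridHash grid;
  grid.h = std::max(2.0 * mean_edge, 1e-8);
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  for (int v = 0; v < nv; ++v)
    for (int j = 0; j < 3; ++j) lo[j] = std::min(lo[j], V[3 * v + j]);
  grid.org[0] = lo[0]; grid.org[1] = lo[1]; grid.org[2] = lo[2];
  for (int f = 0; f < nf; ++f) {
    double bmin[3] = { R_PosInf, R_PosInf, R_PosInf };
    double bmax[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int j = 0; j < 3; ++j) {
      const double* p = &V[3 * F[3 * f + j]];
      for (int d = 0; d < 3; ++d) {
        bmin[d] = std::min(bmin[d], p[d]);
        bmax[d] = std::max(bmax[d], p[d]);
      }
    }
    int i0[3], i1[3];
    for (int d = 0; d < 3; ++d) {
      i0[d] = (int)std::floor((bmin[d] - grid.org[d]) / grid.h);
      i1[d] = (int)std::floor((bmax[d] - grid.org[d]) / grid.h);
    }
    for (int ix = i0[0]; ix <= i1[0]; ++ix)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int iz = i0[2]; iz <= i1[2]; ++iz)
          grid.cells[grid.key(ix, iy, iz)].push_back(f);
  }

  std::vector<int> stamp(nf, -1);
  double anc[3] = { anchor[0], anchor[1], anchor[2] };

  for (int attempt = 0; attempt < 6; ++attempt) {
    double dx = pert * attempt * 0.9170, dy = pert * attempt * 0.3779,
           dz = pert * attempt * 0.4421;
    bool degenerate = false;
    std::vector<double> seg_out, sgn_out, tri_out, px, py, pz, tp_out;

    for (int s = 0; s < nt - 1 && !degenerate; ++s) {
      double p[3] = { tail(s, 0) + dx, tail(s, 1) + dy, tail(s, 2) + dz };
      double q[3] = { tail(s + 1, 0) + dx, tail(s + 1, 1) + dy,
                      tail(s + 1, 2) + dz };
      double dir[3] = { q[0] - p[0], q[1] - p[1], q[2] - p[2] };
      // candidate triangles from the grid
      int c0[3], c1[3];
      for (int d = 0; d < 3; ++d) {
        double a = std::min(p[d], q[d]), b = std::max(p[d], q[d]);
        c0[d] = (int)std::floor((a - grid.org[d]) / grid.h);
        c1[d] = (int)std::floor((b - grid.org[d]) / grid.h);
      }
      for (int ix = c0[0]; ix <= c1[0] && !degenerate; ++ix)
        for (int iy = c0[1]; iy <= c1[1] && !degenerate; ++iy)
          for (int iz = c0[2]; iz <= c1[2] && !degenerate; ++iz) {
            auto it = grid.cells.find(grid.key(ix, iy, iz));
            if (it == grid.cells.end()) continue;
            for (int f : it->second) {
              if (stamp[f] == s + attempt * nt) continue;
              stamp[f] = s + attempt * nt;
              const double* a = &V[3 * F[3 * f]];
              const double* b = &V[3 * F[3 * f + 1]];
              const double* c = &V[3 * F[3 * f + 2]];
              double e1[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
              double e2[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
              double pv[3];
              vcross(dir, e2, pv);
              double det = vdot(e1, pv);
              double nrm[3];
              vcross(e1, e2, nrm);
              double scale = std::sqrt(vdot(nrm, nrm)) *
                             std::sqrt(vdot(dir, dir));
              if (std::fabs(det) < 1e-12 * std::max(scale, 1e-300)) {
                // (near-)parallel segment: in-plane travel is not a
                // transversal crossing; entries/exits are picked up by the
                // neighbouring segments
                continue;
              }
              double inv = 1.0 / det;
              double tv[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
              double u = vdot(tv, pv) * inv;
              if (u < -eps_bary || u > 1.0 + eps_bary) continue;
              double qv[3];
              vcross(tv, e1, qv);
              double v = vdot(dir, qv) * inv;
              if (v < -eps_bary || u + v > 1.0 + eps_bary) continue;
              double t = vdot(e2, qv) * inv;
              if (t < -eps_bary || t > 1.0 + eps_bary) continue;
              double hit[3] = { p[0] + t * dir[0], p[1] + t * dir[1],
                                p[2] + t * dir[2] };
              // anchor exclusion comes first: the tail leaves the surface
              // exactly at the anchor, and no rigid shift of the tail can
              // make that departure transversal
              double da[3] = { hit[0] - anc[0], hit[1] - anc[1],
                               hit[2] - anc[2] };
              if (vdot(da, da) < eps_excl * eps_excl) continue;
              bool inner = (u > eps_bary && v > eps_bary &&
                            u + v < 1.0 - eps_bary && t > eps_bary &&
                            t < 1.0 - eps_bary);
              if (!inner) { degenerate = true; break; }
              if (touches[f]) {
                double db2 = R_PosInf;
                for (int e = 0; e < nb; ++e) {
                  double d2 = point_segment_dist2(hit, &V[3 * e],
                                                  &V[3 * ((e + 1) % nb)]);
                  db2 = std::min(db2, d2);
                }
                if (db2 < eps_excl * eps_excl) continue;
              }
              seg_out.push_back(s + 1);
              tri_out.push_back(f + 1);
              // orientation: + along the consistent triangle normal
              sgn_out.push_back(vdot(dir, nrm) > 0.0 ? 1.0 : -1.0);
              tp_out.push_back(s + t);  // arc-length order key
              px.push_back(hit[0] - dx);
              py.push_back(hit[1] - dy);
              pz.push_back(hit[2] - dz);
            }
          }
    }

    if (!degenerate) {
      int n = (int)seg_out.size();
      std::vector<int> ord(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int i, int j) { return tp_out[i] < tp_out[j]; });
      NumericMatrix out(n, 6);
      for (int i = 0; i < n; ++i) {
        int o = ord[i];
        out(i, 0) = seg_out[o];
        out(i, 1) = tri_out[o];
        out(i, 2) = sgn_out[o];
        out(i, 3) = px[o]; out(i, 4) = py[o]; out(i, 5) = pz[o];
      }
      return List::create(_["crossings"] = out, _["attempt"] = attempt + 1);
    }
    std::fill(stamp.begin(), stamp.end(), -1);
  }
  stop("piercing count failed to resolve degeneracies");
}
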