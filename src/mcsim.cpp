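#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis Monte Carlo of a harmonic-bond, repulsive-r^-12 bead loop,
// optionally threaded on an infinite straight bead line along the x axis
// (periodic images with period `box`).  Thread beads are immobile; the loop
// is kept whole (no wrapping), the minimum image is applied only to
// loop-thread distances.  Moves: single-bead displacements and crankshaft
// rotations of a sub-arc about the chord through its two pivots.  For a
// threaded loop every proposal that would change the winding number of the
// loop about the thread axis is rejected, so threading is conserved exactly.

struct McPar {
  double r0, kbond, A_ll, A_lt, rc2, T, box, ecap;
  int NB;            // thread beads (0 = no thread)
  bool winding;      // enforce winding conservation
};

static inline double pair_e(double A, double r2, const McPar& P) {
  if (r2 >= P.rc2) return 0.0;
  double r6 = r2 * r2 * r2;
  double e = A / (r6 * r6);
  return e > P.ecap ? P.ecap : e;
}

// energy of bead (x,y,z) against the periodic thread bead line
static double thread_e(double x, double y, double z, const McPar& P) {
  if (P.NB <= 0) return 0.0;
  double rho2 = y * y + z * z;
  if (rho2 >= P.rc2) return 0.0;
  double dmax = std::sqrt(P.rc2 - rho2);
  // thread beads at x = j * r0 for all integers j (periodic line)
  int j0 = (int)std::ceil((x - dmax) / P.r0);
  int j1 = (int)std::floor((x + dmax) / P.r0);
  double e = 0.0;
  for (int j = j0; j <= j1; ++j) {
    double dx = x - j * P.r0;
    e += pair_e(P.A_lt, dx * dx + rho2, P);
  }
  return e;
}

static inline double bond_e(const double* a, const double* b,
                            const McPar& P) {
  double d[3] = { a[0] - b[0], a[1] - b[1], a[2] - b[2] };
  double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  return 0.5 * P.kbond * (r - P.r0) * (r - P.r0);
}

static double full_energy(const std::vector<double>& X, int N,
                          const McPar& P) {
  double E = 0.0;
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    E += bond_e(&X[3 * i], &X[3 * j], P);
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 2; j < N; ++j) {
      if (i == 0 && j == N - 1) continue;  // bonded across the seam
      double d[3] = { X[3 * i] - X[3 * j], X[3 * i + 1] - X[3 * j + 1],
                      X[3 * i + 2] - X[3 * j + 2] };
      E += pair_e(P.A_ll, d[0] * d[0] + d[1] * d[1] + d[2] * d[2], P);
    }
  for (int i = 0; i < N; ++i)
    E += thread_e(X[3 * i], X[3 * i + 1], X[3 * i + 2], P);
  return E;
}

// nonbonded + thread energy of bead i in configuration X, skipping beads in
// [skip0, skip1] (cyclic arc, inclusive) in addition to bonded neighbours
static double bead_nb_e(const std::vector<double>& X, int N, int i,
                        int skip0, int skip1, const McPar& P) {
  double E = 0.0;
  const double* xi = &X[3 * i];
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    int dj = std::abs(i - j);
    if (dj == 1 || dj == N - 1) continue;  // bonded
    if (skip0 >= 0) {
      // is j inside the cyclic arc [skip0, skip1]?
      bool inside = (skip0 <= skip1) ? (j >= skip0 && j <= skip1)
                                     : (j >= skip0 || j <= skip1);
      if (inside) continue;
    }
    double d[3] = { xi[0] - X[3 * j], xi[1] - X[3 * j + 1],
                    xi[2] - X[3 * j + 2] };
    E += pair_e(P.A_ll, d[0] * d[0] + d[1] * d[1] + d[2] * d[2], P);
  }
  E += thread_e(xi[0], xi[1], xi[2], P);
  return E;
}

static inline double edge_angle(const std::vector<double>& X, int i, int j) {
  // signed angle increment of the (y,z) projection from bead i to bead j
  double y1 = X[3 * i + 1], z1 = X[3 * i + 2];
  double y2 = X[3 * j + 1], z2 = X[3 * j + 2];
  return std::atan2(y1 * z2 - z1 * y2, y1 * y2 + z1 * z2);
}

// [[Rcpp::export]]
double cpp_winding_number(NumericMatrix loop) {
  int N = loop.nrow();
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    int j = (i + 1) % N;
    double y1 = loop(i, 1), z1 = loop(i, 2);
    double y2 = loop(j, 1), z2 = loop(j, 2);
    s += std::atan2(y1 * z2 - z1 * y2, y1 * y2 + z1 * z2);
  }
  return s / (2.0 * M_PI);
}

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix loop, List par) {
  McPar P;
  P.r0 = par["r0"]; P.kbond = par["kbond"]; P.A_ll = par["A_ll"];
  P.A_lt = par["A_lt"]; P.rc2 = par["rc2"]; P.T = par["T"];
  P.box = par["box"]; P.ecap = par["ecap"]; P.NB = par["NB"];
  int N = loop.nrow();
  std::vector<double> X(3 * N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < 3; ++j) X[3 * i + j] = loop(i, j);
  return full_energy(X, N, P);
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix loop0, List par, int sweeps, int stride,
                int tune_sweeps, double disp0, double ang0) {
  McPar P;
  P.r0 = par["r0"]; P.kbond = par["kbond"]; P.A_ll = par["A_ll"];
  P.A_lt = par["A_lt"]; P.rc2 = par["rc2"]; P.T = par["T"];
  P.box = par["box"]; P.ecap = par["ecap"]; P.NB = par["NB"];
  P.winding = as<bool>(par["winding"]);

  int N = loop0.nrow();
  std::vector<double> X(3 * N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < 3; ++j) X[3 * i + j] = loop0(i, j);

  // per-edge winding increments (threaded case)
  std::vector<double> dth(N, 0.0);
  double wsum = 0.0;
  int W0 = 0;
  if (P.winding) {
    for (int i = 0; i < N; ++i) {
      dth[i] = edge_angle(X, i, (i + 1) % N);
      wsum += dth[i];
    }
    W0 = (int)std::lround(wsum / (2.0 * M_PI));
    if (std::abs(W0) != 1) stop("initial loop is not singly threaded");
  }

  double E = full_energy(X, N, P);
  double disp = disp0, ang = ang0;
  long acc_d = 0, try_d = 0, acc_c = 0, try_c = 0;
  int mmax = std::max(2, N / 2);

  int nrec = sweeps / stride;
  NumericVector frames((R_xlen_t)nrec * N * 3);
  NumericVector energies(nrec);
  IntegerVector threaded(nrec);
  int rec = 0;

  std::vector<double> Y;     // proposal scratch for crank
  std::vector<double> ndth(N);

  for (int sweep = -tune_sweeps; sweep < sweeps; ++sweep) {
    for (int mv = 0; mv < N; ++mv) {
      if (unif_rand() < 0.5) {
        // --- single-bead displacement --------------------------------
        ++try_d;
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        double old_[3] = { X[3 * i], X[3 * i + 1], X[3 * i + 2] };
        double nw[3] = { old_[0] + disp * (2.0 * unif_rand() - 1.0),
                         old_[1] + disp * (2.0 * unif_rand() - 1.0),
                         old_[2] + disp * (2.0 * unif_rand() - 1.0) };
        int im = (i - 1 + N) % N, ip = (i + 1) % N;
        double e_old = bond_e(old_, &X[3 * im], P) +
                       bond_e(old_, &X[3 * ip], P) +
                       bead_nb_e(X, N, i, -1, -1, P);
        X[3 * i] = nw[0]; X[3 * i + 1] = nw[1]; X[3 * i + 2] = nw[2];
        double e_new = bond_e(nw, &X[3 * im], P) +
                       bond_e(nw, &X[3 * ip], P) +
                       bead_nb_e(X, N, i, -1, -1, P);
        bool ok = true;
        double d_im = 0, d_i = 0;
        if (P.winding) {
          if (nw[1] * nw[1] + nw[2] * nw[2] < 1e-20) ok = false;
          if (ok) {
            d_im = edge_angle(X, im, i);
            d_i = edge_angle(X, i, ip);
            double ns = wsum - dth[im] - dth[i] + d_im + d_i;
            if ((int)std::lround(ns / (2.0 * M_PI)) != W0) ok = false;
          }
        }
        double dE = e_new - e_old;
        if (ok && (dE <= 0.0 || unif_rand() < std::exp(-dE / P.T))) {
          E += dE;
          ++acc_d;
          if (P.winding) {
            wsum += d_im + d_i - dth[im] - dth[i];
            dth[im] = d_im; dth[i] = d_i;
          }
        } else {
          X[3 * i] = old_[0]; X[3 * i + 1] = old_[1]; X[3 * i + 2] = old_[2];
        }
      } else {
        // --- crankshaft rotation -------------------------------------
        ++try_c;
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        int m = 2 + (int)(unif_rand() * (mmax - 1));   // pivot offset 2..mmax
        int j = (i + m) % N;
        // moved beads: cyclic arc (i+1 .. i+m-1)
        int a0 = (i + 1) % N, a1 = (j - 1 + N) % N;
        double th = ang * (2.0 * unif_rand() - 1.0);
        double axv[3] = { X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                          X[3 * j + 2] - X[3 * i + 2] };
        double an = std::sqrt(axv[0] * axv[0] + axv[1] * axv[1] +
                              axv[2] * axv[2]);
        if (an < 1e-12) continue;
        axv[0] /= an; axv[1] /= an; axv[2] /= an;
        double ct = std::cos(th), st = std::sin(th);

        // old cross-arc energy
        double e_old = 0.0;
        for (int kk = 0; kk < m - 1; ++kk) {
          int b = (i + 1 + kk) % N;
          e_old += bead_nb_e(X, N, b, a0, a1, P);
        }
        // propose
        Y.assign(X.begin(), X.end());
        for (int kk = 0; kk < m - 1; ++kk) {
          int b = (i + 1 + kk) % N;
          double v[3] = { X[3 * b] - X[3 * i], X[3 * b + 1] - X[3 * i + 1],
                          X[3 * b + 2] - X[3 * i + 2] };
          double ad = axv[0] * v[0] + axv[1] * v[1] + axv[2] * v[2];
          double cx[3] = { axv[1] * v[2] - axv[2] * v[1],
                           axv[2] * v[0] - axv[0] * v[2],
                           axv[0] * v[1] - axv[1] * v[0] };
          for (int d = 0; d < 3; ++d)
            Y[3 * b + d] = X[3 * i + d] + v[d] * ct + cx[d] * st +
                           axv[d] * ad * (1.0 - ct);
        }
        double e_new = 0.0;
        for (int kk = 0; kk < m - 1; ++kk) {
          int b = (i + 1 + kk) % N;
          e_new += bead_nb_e(Y, N, b, a0, a1, P);
        }
        bool ok = true;
        double dws = 0.0;
        if (P.winding) {
          // edges i..j-1 (cyclic) change
          for (int kk = 0; kk < m; ++kk) {
            int e = (i + kk) % N;
            int f = (e + 1) % N;
            if (Y[3 * f + 1] * Y[3 * f + 1] + Y[3 * f + 2] * Y[3 * f + 2] <
                1e-20) { ok = false; break; }
            ndth[e] = edge_angle(Y, e, f);
            dws += ndth[e] - dth[e];
          }
          if (ok &&
              (int)std::lround((wsum + dws) / (2.0 * M_PI)) != W0) ok = false;
        }
        double dE = e_new - e_old;
        if (ok && (dE <= 0.0 || unif_rand() < std::exp(-dE / P.T))) {
          X.swap(Y);
          E += dE;
          ++acc_c;
          if (P.winding) {
            for (int kk = 0; kk < m; ++kk) {
              int e = (i + kk) % N;
              dth[e] = ndth[e];
            }
            wsum += dws;
          }
        }
      }
    }

    // amplitude tuning towards 30-50% acceptance, frozen after burn-in
    if (sweep < 0 && ((sweep + tune_sweeps) % 20 == 19 || sweep == -1)) {
      if (try_d > 0) {
        double r = (double)acc_d / try_d;
        if (r > 0.5) disp = std::min(disp * 1.25, 5.0 * P.r0);
        if (r < 0.3) disp = std::max(disp * 0.8, 1e-4 * P.r0);
      }
      if (try_c > 0) {
        double r = (double)acc_c / try_c;
        if (r > 0.5) ang = std::min(ang * 1.25, M_PI);
        if (r < 0.3) ang = std::max(ang * 0.8, 1e-4);
      }
      acc_d = try_d = acc_c = try_c = 0;
    }

    if (sweep >= 0 && (sweep + 1) % stride == 0 && rec < nrec) {
      E = full_energy(X, N, P);  // resync against incremental drift
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)rec * N * 3 + i + (R_xlen_t)d * N] = X[3 * i + d];
      energies[rec] = E;
      if (P.winding) {
        NumericMatrix fr(N, 3);
        for (int i = 0; i < N; ++i)
          for (int d = 0; d < 3; ++d) fr(i, d) = X[3 * i + d];
        threaded[rec] =
            std::abs(std::lround(cpp_winding_number(fr))) == 1 ? 1 : 0;
      } else {
        threaded[rec] = NA_INTEGER;
      }
      ++rec;
    }
  }

  frames.attr("dim") = IntegerVector::create(N, 3, nrec);
  double accd = try_d > 0 ? (double)acc_d / try_d : NA_REAL;
  double accc = try_c > 0 ? (double)acc_c / try_c : NA_REAL;
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["threaded"] = threaded, _["acc_disp"] = accd,
                      _["acc_crank"] = accc, _["disp"] = disp,
                      _["ang"] = ang);
}
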