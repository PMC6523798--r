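# Metropolis Monte Carlo of an excluded-volume bead loop, optionally
# threaded on an infinite periodic thread of variable thickness.  The model
# is a coarse-grained C-alpha-like bead chain: harmonic bonds with
# equilibrium length r0 = 0.38 nm and force constant 20,000 eps/nm^2,
# repulsive A/r^12 excluded volume with A = 0.16777216e-4 kJ nm^12/mol cut
# at 2 nm, no angular or attractive terms.  The thread is a straight
# immobile bead line along the x axis made effectively infinite by periodic
# images; its beads are w times thicker than loop beads.

N_SMALL <- c(`0` = 3L, `1` = 4L, `2` = 6L, `3` = 7L, `4` = 7L)

#' Smallest loop that fits around a thread of thickness factor w
#' @param w Thread thickness factor (0-4).
#' @return Minimal loop bead count.
#' @export
n_small <- function(w) {
  stopifnot(w %in% 0:4)
  unname(N_SMALL[as.character(w)])
}

#' Simulation configuration for the threaded-loop model
#'
#' @param N Loop bead count (at least [n_small()]`(w)`).
#' @param w Thread thickness factor in 0:4; `w = 0` means no thread at all
#'   (the unthreaded reference loop).
#' @param T Temperature in reduced (Gromacs) units, i.e. Kelvin with
#'   energies in kJ/mol: the Metropolis weight is exp(-dE / (kB T)) with
#'   kB = 0.0083144621 kJ/(mol K).  The study temperatures are
#'   T in \{10, 50, 100\}; at the highest the chain is most flexible.
#' @param sweeps Production sweeps (one sweep = N attempted moves).
#' @param stride Record a frame every `stride` sweeps.
#' @param tune_sweeps Pre-production sweeps during which move amplitudes
#'   are tuned towards 30-50% acceptance, then frozen.
#' @param seed Optional integer seed applied before the run.
#' @return A `sim_config` list including the derived thread bead count
#'   `N_B = max(ceiling(N/2) + 5, 12)` and periodic box length
#'   `0.38 * N_B` nm.
#' @export
sim_config <- function(N, w = 0L, T = 100, sweeps = 2000L, stride = 1L,
                       tune_sweeps = 200L, seed = NULL) {
  stopifnot(w %in% 0:4, T > 0, sweeps >= 1, stride >= 1)
  if (N < n_small(w))
    stop(sprintf(
      "too-small-loop: N = %d but the smallest loop around a thread of thickness %d is %d beads",
      N, w, n_small(w)))
  r0 <- 0.38
  kB <- 0.0083144621  # kJ/(mol K), Gromacs units
  NB <- if (w > 0) max(ceiling(N / 2) + 5, 12L) else 0L
  structure(list(
    N = as.integer(N), w = as.integer(w), T = T, kT = kB * T,
    r0 = r0, kbond = 20000, vdw_A = 0.16777216e-4, vdw_cutoff = 2,
    # loop-thread repulsion scaled so the contact radius is the additive
    # mean of a unit-radius loop bead and a w-times-thicker thread bead
    A_thread = 0.16777216e-4 * ((1 + w) / 2)^12,
    N_B = as.integer(NB), box = r0 * NB, ecap = 1e6,
    sweeps = as.integer(sweeps), stride = as.integer(stride),
    tune_sweeps = as.integer(tune_sweeps), seed = seed),
    class = "sim_config")
}

cpp_par <- function(config) {
  list(r0 = config$r0, kbond = config$kbond, A_ll = config$vdw_A,
       A_lt = config$A_thread, rc2 = config$vdw_cutoff^2, T = config$kT,
       box = config$box, ecap = config$ecap, NB = config$N_B,
       winding = config$w > 0)
}

#' Build the initial frame of the threaded-loop system
#'
#' Thread beads (if any) sit on a straight line along the x axis at spacing
#' r0, replicated periodically.  The loop starts as a planar regular N-gon
#' with edge length r0; for `w > 0` it lies in a plane perpendicular to the
#' thread and encircles it (winding number +1), for `w = 0` it floats
#' freely at the origin.
#'
#' @param config A [sim_config()].
#' @return A `sim_frame`: list with `loop` (N x 3 matrix, nm), `step = 0`
#'   and `energy`.
#' @export
build_system <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  R <- config$r0 / (2 * sin(pi / N))
  theta <- 2 * pi * (seq_len(N) - 1) / N
  if (config$w > 0) {
    x0 <- config$box / 2
    loop <- cbind(rep(x0, N), R * cos(theta), R * sin(theta))
  } else {
    loop <- cbind(R * cos(theta), R * sin(theta), rep(0, N))
  }
  structure(list(loop = loop, step = 0L,
                 energy = potential_energy(loop, config)),
            class = "sim_frame")
}

#' Potential energy of a loop configuration
#'
#' Harmonic bond terms plus repulsive A/r^12 excluded volume between all
#' non-bonded loop bead pairs and between loop beads and the periodic
#' thread bead line (minimum image along the thread axis, 2 nm cutoff).
#' Individual pair energies are capped at `ecap` so overlapping beads keep
#' the Metropolis rule well defined.
#'
#' @param frame A `sim_frame` or an N x 3 coordinate matrix (nm).
#' @param config A [sim_config()].
#' @return Scalar energy in eps units.
#' @export
potential_energy <- function(frame, config) {
  loop <- if (inherits(frame, "sim_frame")) frame$loop else as.matrix(frame)
  stopifnot(ncol(loop) == 3L, all(is.finite(loop)))
  cpp_potential_energy(loop, cpp_par(config))
}

#' Does the loop still wind around the thread axis?
#'
#' True iff the winding number of the loop's (y, z) projection about the
#' thread axis is exactly +1 or -1.  The winding number is invariant under
#' any loop deformation that never crosses the axis.
#'
#' @param frame A `sim_frame` or coordinate matrix.
#' @param config A [sim_config()] with `w > 0`.
#' @return Logical.
#' @export
check_threading <- function(frame, config) {
  stopifnot(config$w > 0)
  loop <- if (inherits(frame, "sim_frame")) frame$loop else as.matrix(frame)
  abs(round(cpp_winding_number(loop))) == 1
}

#' Run the Metropolis Monte Carlo simulation
#'
#' Move set: single-bead displacements and crankshaft rotations of a random
#' sub-arc about the chord through its pivots, accepted with probability
#' min(1, exp(-dE / T)).  Thread beads never move.  For `w > 0` every
#' proposal that would change the loop's winding number about the thread is
#' rejected, so threading is conserved exactly; every recorded frame is
#' re-checked.  Frames are recorded every `stride` sweeps after the tuning
#' phase; the burn-in implied by the chord correlation function (three
#' times the lag at which it decays to 0.1) is reported and removed via
#' [discard_burnin()].
#'
#' @param config A [sim_config()].
#' @return A `lasso_trajectory`: list with `frames` (N x 3 x n_frames
#'   array), `energies`, `threaded` (per-frame winding check, `NA` for
#'   w = 0), `config`, acceptance rates and tuned move amplitudes.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- build_system(config)
  res <- cpp_mc_run(init$loop, cpp_par(config), config$sweeps,
                    config$stride, config$tune_sweeps,
                    disp0 = 0.5 * config$r0, ang0 = 0.5)
  if (config$w > 0 && any(res$threaded == 0L))
    stop("internal error: threading violated by an accepted move")
  structure(list(frames = res$frames, energies = res$energies,
                 threaded = res$threaded, config = config,
                 acc_disp = res$acc_disp, acc_crank = res$acc_crank,
                 disp = res$disp, ang = res$ang),
            class = "lasso_trajectory")
}

#' Chord correlation function of a trajectory
#'
#' `C(tau)` is the average over chords (bond vectors) and time origins of
#' the dot product of unit chord vectors separated by `tau` recorded
#' frames, normalised so `C(0) = 1`.  `tau_01` is the first lag at which
#' `C` drops to 0.1; the burn-in is three times that.
#'
#' @param traj A `lasso_trajectory` or an N x 3 x F frame array.
#' @param lags Integer lags (in recorded frames) at which to evaluate.
#' @param tau_required Raise an insufficient-sampling error when `C` never
#'   reaches 0.1 within the run (set by [discard_burnin()], which needs
#'   `tau_01`); with the default `FALSE` a non-decaying correlation simply
#'   yields `tau_01 = NA` (e.g., identical repeated frames have C = 1 at
#'   every lag).
#' @return List with `lags`, `C`, `tau_01`, `burn_in`.
#' @export
chord_correlation <- function(traj, lags = NULL, tau_required = FALSE) {
  fr <- if (inherits(traj, "lasso_trajectory")) traj$frames else traj
  stopifnot(length(dim(fr)) == 3L)
  nf <- dim(fr)[3L]
  if (nf < 2L) stop("need at least 2 recorded frames")
  auto_lags <- is.null(lags)
  if (auto_lags) {
    # the decay to 0.1 usually happens within a few frames; start with a
    # short lag window and let the caller's loop below extend it instead
    # of paying for every lag up front
    lags <- 0:min(nf - 1L, 64L)
  }
  lags <- sort(unique(as.integer(lags)))
  stopifnot(all(lags >= 0), all(lags < nf))
  N <- dim(fr)[1L]
  # unit chord (bond) vectors per frame: N x 3 x F
  u <- fr[c(2:N, 1L), , , drop = FALSE] - fr
  nrm <- sqrt(u[, 1L, , drop = FALSE]^2 + u[, 2L, , drop = FALSE]^2 +
                u[, 3L, , drop = FALSE]^2)[, 1L, ]
  for (d in 1:3) u[, d, ] <- u[, d, ] / nrm
  C <- vapply(lags, function(tau) {
    idx <- seq_len(nf - tau)
    a <- u[, , idx, drop = FALSE]
    b <- u[, , idx + tau, drop = FALSE]
    mean(a[, 1L, ] * b[, 1L, ] + a[, 2L, ] * b[, 2L, ] +
           a[, 3L, ] * b[, 3L, ])
  }, 0)
  below <- which(C <= 0.1)
  # extend the automatic lag window geometrically until the decay (if any)
  # is bracketed
  while (auto_lags && !length(below) && max(lags) < nf - 1L) {
    ext <- seq(max(lags) + 1L, min(nf - 1L, max(lags) * 4L + 4L))
    Ce <- vapply(ext, function(tau) {
      idx <- seq_len(nf - tau)
      a <- u[, , idx, drop = FALSE]
      b <- u[, , idx + tau, drop = FALSE]
      mean(a[, 1L, ] * b[, 1L, ] + a[, 2L, ] * b[, 2L, ] +
             a[, 3L, ] * b[, 3L, ])
    }, 0)
    lags <- c(lags, ext)
    C <- c(C, Ce)
    below <- which(C <= 0.1)
  }
  tau_01 <- if (length(below)) lags[min(below)] else NA_integer_
  if (is.na(tau_01) && tau_required)
    stop(sprintf(
      "insufficient-sampling: chord correlation never reached 0.1 (min %.3f)",
      min(C)))
  list(lags = lags, C = C, tau_01 = tau_01,
       burn_in = if (is.na(tau_01)) NA_integer_ else 3L * tau_01)
}

#' Drop burn-in frames from a trajectory
#'
#' Removes the first `3 * tau_01` recorded frames as determined by
#' [chord_correlation()] (or an explicit frame count).
#'
#' @param traj A `lasso_trajectory`.
#' @param burn_in Optional explicit number of frames to drop; when missing
#'   the chord-correlation rule is applied.
#' @return The trimmed `lasso_trajectory` with `tau_01` recorded in
#'   `decorrelation`.
#' @export
discard_burnin <- function(traj, burn_in = NULL) {
  stopifnot(inherits(traj, "lasso_trajectory"))
  cc <- NULL
  if (is.null(burn_in)) {
    cc <- chord_correlation(traj, tau_required = TRUE)
    burn_in <- cc$burn_in
  }
  nf <- dim(traj$frames)[3L]
  if (burn_in >= nf)
    stop("insufficient-sampling: burn-in would discard every frame")
  keep <- (burn_in + 1L):nf
  traj$frames <- traj$frames[, , keep, drop = FALSE]
  traj$energies <- traj$energies[keep]
  traj$threaded <- traj$threaded[keep]
  traj$decorrelation <- list(tau_01 = if (is.null(cc)) NA_integer_ else
    cc$tau_01, burn_in = burn_in)
  traj
}

#' @export
print.lasso_trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: N = %d, w = %d, T = %g, %d frames (stride %d sweeps)\n",
    x$config$N, x$config$w, x$config$T, dim(x$frames)[3L],
    x$config$stride))
  invisible(x)
}
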