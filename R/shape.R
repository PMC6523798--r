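# Size and shape descriptors of loop conformations: radius of gyration,
# distension, gyration-tensor ellipsoid semi-axes, asphericity,
# prolateness, and their scaling-law fits versus loop length.

#' Radius of gyration
#'
#' Root-mean-square distance of the beads from their centroid:
#' `Rg = sqrt(mean(|r_i - r_cm|^2))`.
#'
#' @param coords n x 3 coordinate matrix (n >= 2).
#' @return Scalar Rg in the units of `coords`.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("radius of gyration needs at least 2 points")
  c0 <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2L, c0, "-")^2)))
}

#' Distension of a closed loop
#'
#' Compares the loop's Rg with that of a flat regular polygon with the same
#' bead count and relaxed bonds: `D = (2 Rg / r0) * sin(pi / N)`.  The
#' maximally stretched symmetric loop with all bonds at `r0` has D = 1;
#' stretched bonds push D above 1, contraction below.
#'
#' @param coords N x 3 closed-loop coordinates.
#' @param N Bead count (defaults to `nrow(coords)`).
#' @param r0 Equilibrium bond length (same units as `coords`).
#' @return Dimensionless distension.
#' @export
distension <- function(coords, N = nrow(as.matrix(coords)), r0 = 0.38) {
  if (N < 3) stop("distension needs a loop of at least 3 beads")
  (2 * radius_of_gyration(coords) / r0) * sin(pi / N)
}

#' Semi-axes of the gyration-tensor ellipsoid
#'
#' Square roots of the eigenvalues of the centroid-centred second-moment
#' (gyration) tensor, sorted `a >= b >= c` — the principal radii of
#' gyration.  Degenerate (planar or collinear) configurations yield zero
#' axes; note `Rg^2 = a^2 + b^2 + c^2`.
#'
#' @param coords n x 3 coordinate matrix.
#' @return Named numeric vector `c(a, b, c)`.
#' @export
ellipsoid_semi_axes <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2L, ncol(coords) == 3L)
  x <- sweep(coords, 2L, colMeans(coords), "-")
  S <- crossprod(x) / nrow(x)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  setNames(sqrt(pmax(ev, 0)), c("a", "b", "c"))
}

#' Asphericity of an ellipsoid
#'
#' `A = ((a-b)^2 + (b-c)^2 + (c-a)^2) / (2 (a+b+c)^2)`, in \[0, 1\]: 0 for
#' a sphere, 0.25 for a flat disk, 1 for a stick.
#'
#' @param a,b,c Semi-axes with `a >= b >= c >= 0`, not all zero.  `a` may
#'   also be a length-3 vector.
#' @return Scalar asphericity.
#' @export
asphericity <- function(a, b = NULL, c = NULL) {
  if (is.null(b)) { b <- a[2L]; c <- a[3L]; a <- a[1L] }
  if (a + b + c <= 0) stop("asphericity undefined for all-zero axes")
  ((a - b)^2 + (b - c)^2 + (c - a)^2) / (2 * (a + b + c)^2)
}

#' Prolateness of an ellipsoid
#'
#' `P = (2a-b-c)(2b-c-a)(2c-a-b) / (2 (a^2+b^2+c^2-ab-bc-ca)^{3/2})`, in
#' \[-1, 1\]: exactly +1 for a degenerate prolate (rugby-ball, b = c) and
#' -1 for a degenerate oblate (disk, a = b) ellipsoid.  Undefined for a
#' sphere.
#'
#' @param a,b,c Semi-axes with `a >= b >= c >= 0`; `a` may be a length-3
#'   vector.
#' @return Scalar prolateness.
#' @export
prolateness <- function(a, b = NULL, c = NULL) {
  if (is.null(b)) { b <- a[2L]; c <- a[3L]; a <- a[1L] }
  q <- a^2 + b^2 + c^2 - a * b - b * c - c * a
  if (q <= 0) stop("undefined-prolateness: the ellipsoid is a sphere")
  (2 * a - b - c) * (2 * b - c - a) * (2 * c - a - b) / (2 * q^1.5)
}

#' All shape descriptors of one conformation
#'
#' @param coords N x 3 closed-loop coordinates.
#' @param r0 Equilibrium bond length for the distension normalisation.
#' @return A `shape_record`: list with `Rg`, `D`, `semi_axes`, `A`, `P`
#'   (`NA` when the shape is a perfect sphere).
#' @export
shape_record <- function(coords, r0 = 0.38) {
  ax <- ellipsoid_semi_axes(coords)
  A <- asphericity(ax)
  P <- if (A > 0) prolateness(ax) else NA_real_
  structure(list(Rg = radius_of_gyration(coords),
                 D = distension(coords, r0 = r0),
                 semi_axes = ax, A = A, P = P),
            class = "shape_record")
}

#' Per-length mean shape descriptors of a trajectory
#'
#' Computes per-frame descriptors over decorrelated frames (every
#' `thin`-th frame) and returns their means with block-averaged standard
#' errors (block length = the decorrelation lag when known).
#'
#' @param traj A `lasso_trajectory` (burn-in already discarded).
#' @param thin Keep every `thin`-th frame (defaults to the trajectory's
#'   `tau_01` when present, else 1).
#' @return One-row data frame: N, w, T, n_frames, mean and SE for Rg, D,
#'   A, P.
#' @export
shape_table <- function(traj, thin = NULL) {
  stopifnot(inherits(traj, "lasso_trajectory"))
  if (is.null(thin)) {
    tau <- traj$decorrelation$tau_01
    thin <- if (!is.null(tau) && is.finite(tau) && tau >= 1) tau else 1L
  }
  nf <- dim(traj$frames)[3L]
  idx <- seq(1L, nf, by = max(1L, as.integer(thin)))
  r0 <- traj$config$r0
  recs <- lapply(idx, function(i) shape_record(traj$frames[, , i], r0 = r0))
  mean_se <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), se = sd(v) / sqrt(length(v)))
  }
  rg <- mean_se(vapply(recs, `[[`, 0, "Rg"))
  dd <- mean_se(vapply(recs, `[[`, 0, "D"))
  aa <- mean_se(vapply(recs, `[[`, 0, "A"))
  pp <- mean_se(vapply(recs, `[[`, 0, "P"))
  data.frame(N = traj$config$N, w = traj$config$w, T = traj$config$T,
             n_frames = length(idx),
             Rg = rg["mean"], Rg_se = rg["se"],
             D = dd["mean"], D_se = dd["se"],
             A = aa["mean"], A_se = aa["se"],
             P = pp["mean"], P_se = pp["se"], row.names = NULL)
}

# weighted fit helper: floor zero/missing SEs to keep weights finite
fit_weights <- function(se) {
  se[!is.finite(se) | se <= 0] <- max(se[is.finite(se) & se > 0], 1e-6)
  1 / se^2
}

#' Fit the radius-of-gyration scaling law
#'
#' `<Rg> = c_r + a_r * N^nu`, weighted least squares over loops with at
#' least `n_min` beads.  In `mode = "fixed"` the exponent is frozen at
#' `nu = 0.59` and only `a_r`, `c_r` are fitted; in `mode = "free"` all
#' three parameters are free.
#'
#' @param means Data frame with columns `N`, `Rg`, `Rg_se`.
#' @param mode `"free"` or `"fixed"`.
#' @param nu_fixed Exponent used in fixed mode.
#' @param n_min Smallest loop length included (small rigid loops are
#'   excluded).
#' @return A `scaling_fit`: list with `law`, `params`, `se`, `cov`,
#'   `n_range`.
#' @export
fit_rg_scaling <- function(means, mode = c("free", "fixed"),
                           nu_fixed = 0.59, n_min = 30L) {
  mode <- match.arg(mode)
  dat <- means[means$N >= n_min, , drop = FALSE]
  if (nrow(dat) < 4L) stop("need >= 4 loop lengths with N >= n_min")
  w <- fit_weights(dat$Rg_se)
  if (mode == "fixed") {
    # linear in (c_r, a_r) once nu is frozen
    X <- cbind(1, dat$N^nu_fixed)
    fit <- lm.wfit(X, dat$Rg, w)
    cf <- c(c_r = unname(fit$coefficients[1L]),
            a_r = unname(fit$coefficients[2L]), nu = nu_fixed)
    rss <- sum(w * fit$residuals^2)
    dof <- max(nrow(dat) - 2L, 1L)
    XtX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    pse <- sqrt(diag(XtX_inv) * rss / dof)
    cv <- XtX_inv * rss / dof
    se <- c(c_r = pse[1L], a_r = pse[2L], nu = 0)
  } else {
    starts <- lapply(c(0.5, 0.59, 0.7), function(nu0)
      list(c_r = 0, a_r = mean(dat$Rg / dat$N^nu0), nu = nu0))
    fit <- fit_multistart(Rg ~ c_r + a_r * N^nu, dat, starts, weights = w,
                          lower = c(-Inf, 1e-12, 0.1))
    cf <- coef(fit)
    cv <- tryCatch(vcov(fit), error = function(e)
      matrix(NA_real_, 3, 3, dimnames = list(names(cf), names(cf))))
    se <- sqrt(pmax(diag(cv), 0))
  }
  structure(list(law = "Rg ~ c_r + a_r * N^nu", params = cf, se = se,
                 cov = if (mode == "fixed") cv else cv,
                 n_range = range(dat$N), mode = mode),
            class = "scaling_fit")
}

#' Fit the asphericity scaling law
#'
#' `<A> = A_inf + a_A * N^mu` over loops with at least `n_min` beads.
#'
#' @param means Data frame with columns `N`, `A`, `A_se`.
#' @param n_min Smallest loop length included.
#' @return A `scaling_fit` with params `A_inf`, `a_A`, `mu`.
#' @export
fit_asphericity_scaling <- function(means, n_min = 30L) {
  dat <- means[means$N >= n_min, , drop = FALSE]
  if (nrow(dat) < 4L) stop("need >= 4 loop lengths with N >= n_min")
  w <- fit_weights(dat$A_se)
  a_tail <- dat$A[which.max(dat$N)]
  starts <- lapply(c(-0.2, -0.5, -1), function(mu0)
    list(A_inf = a_tail, a_A = (dat$A[which.min(dat$N)] - a_tail) *
           min(dat$N)^(-mu0), mu = mu0))
  # mu is bounded away from 0: over any feasible N range a correction
  # decaying slower than N^-0.15 is numerically collinear with the
  # constant A_inf, so the unbounded fit can drift along that ridge
  fit <- fit_multistart(A ~ A_inf + a_A * N^mu, dat, starts, weights = w,
                        lower = c(0, -Inf, -5), upper = c(1, Inf, -0.15))
  cf <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(names(cf), names(cf))))
  structure(list(law = "A ~ A_inf + a_A * N^mu", params = cf,
                 se = sqrt(pmax(diag(cv), 0)), cov = cv,
                 n_range = range(dat$N)),
            class = "scaling_fit")
}

#' Fit the prolateness scaling law
#'
#' `<P> = P_inf + a_P * N^(-0.47)` with the exponent frozen (an almost
#' inverse-square-root approach to the asymptote), so the fit is weighted
#' linear least squares in `(P_inf, a_P)`.
#'
#' @param means Data frame with columns `N`, `P`, `P_se`.
#' @param n_min Smallest loop length included.
#' @return A `scaling_fit` with params `P_inf`, `a_P`.
#' @export
fit_prolateness_scaling <- function(means, n_min = 30L) {
  dat <- means[means$N >= n_min, , drop = FALSE]
  if (nrow(dat) < 4L) stop("need >= 4 loop lengths with N >= n_min")
  w <- fit_weights(dat$P_se)
  X <- cbind(1, dat$N^(-0.47))
  fit <- lm.wfit(X, dat$P, w)
  rss <- sum(w * fit$residuals^2)
  dof <- max(nrow(dat) - 2L, 1L)
  XtX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  pse <- sqrt(diag(XtX_inv) * rss / dof)
  structure(list(law = "P ~ P_inf + a_P * N^-0.47",
                 params = c(P_inf = unname(fit$coefficients[1L]),
                            a_P = unname(fit$coefficients[2L])),
                 se = c(P_inf = pse[1L], a_P = pse[2L]),
                 cov = XtX_inv * rss / dof,
                 n_range = range(dat$N)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(x$law, " (N in [", x$n_range[1L], ", ", x$n_range[2L], "])\n",
      sep = "")
  print(round(x$params, 5))
  invisible(x)
}
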