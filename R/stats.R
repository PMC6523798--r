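# Ensemble statistics: class tables, double-exponential decay fits of the
# trivial-lasso probability, domination number, geometric piercing model.

#' Tabulate classified lassos into per-cell class counts and spectra
#'
#' @param classified Data frame with columns `N`, `t`, `class`,
#'   `n_piercings` (one row per classified lasso).
#' @return An `ensemble_table`: list with `classes` (per (N, t, class):
#'   count, probability, binomial SE), `spectrum` (per (N, t,
#'   n_piercings): count), and `cells` (per (N, t): sample count).  Empty
#'   cells never appear; binomial SE = sqrt(p(1-p)/n).
#' @export
tabulate_ensemble <- function(classified) {
  stopifnot(all(c("N", "t", "class", "n_piercings") %in% names(classified)))
  if (nrow(classified) == 0L) stop("no classified lassos to tabulate")
  cells <- aggregate(cbind(n = rep(1L, nrow(classified))) ~ N + t,
                     data = classified, FUN = sum)
  cls <- aggregate(cbind(count = rep(1L, nrow(classified))) ~ N + t + class,
                   data = classified, FUN = sum)
  cls <- merge(cls, cells, by = c("N", "t"))
  cls$probability <- cls$count / cls$n
  cls$se <- sqrt(cls$probability * (1 - cls$probability) / cls$n)
  spec <- aggregate(cbind(count = rep(1L, nrow(classified))) ~ N + t +
                      n_piercings, data = classified, FUN = sum)
  structure(list(classes = cls[order(cls$N, cls$t, cls$class), ],
                 spectrum = spec[order(spec$N, spec$t, spec$n_piercings), ],
                 cells = cells),
            class = "ensemble_table")
}

#' Per-cell trivial-lasso probability from an ensemble table
#'
#' @param table An `ensemble_table`.
#' @param along `"N"`, `"t"`, or `"both"`; which variables to keep.
#' @return Data frame with `N`, `t`, `p` (probability of class L0), `se`,
#'   `n`.  Cells with no L0 samples get p = 0 with the SE floored at
#'   1/(2n); cells with only L0 get p = 1 with the same floor.
#' @export
trivial_probability <- function(table, along = "both") {
  stopifnot(inherits(table, "ensemble_table"))
  cells <- table$cells
  l0 <- table$classes[table$classes$class == "L0",
                      c("N", "t", "count")]
  out <- merge(cells, l0, by = c("N", "t"), all.x = TRUE)
  out$count[is.na(out$count)] <- 0L
  out$p <- out$count / out$n
  out$se <- sqrt(out$p * (1 - out$p) / out$n)
  floor_se <- 1 / (2 * out$n)
  out$se <- pmax(out$se, floor_se)
  out[order(out$N, out$t), c("N", "t", "p", "se", "n")]
}

# shared multi-start weighted nonlinear least squares
# (weights live in the data frame: nls() resolves the weights argument in
# the formula environment, not here)
fit_multistart <- function(formula, data, starts, weights, lower,
                           upper = NULL) {
  data$.w <- weights
  if (is.null(upper)) upper <- rep(Inf, length(lower))
  best <- NULL
  best_rss <- Inf
  best_msg <- "no start converged"
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        weights = .w, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12)),
      error = function(e) { best_msg <<- conditionMessage(e); NULL })
    if (!is.null(fit)) {
      rss <- sum(weights * residuals(fit)^2)
      if (is.finite(rss) && rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (!is.null(best)) return(best)
  # Fallback: drive Levenberg-Marquardt directly.  The nls wrapper around
  # it refuses rank-deficient Jacobians at the solution (e.g., when a
  # fast-rate exponential has died out on every grid point), which the
  # damped optimiser itself handles fine.
  rhs <- formula[[3L]]
  lhs <- eval(formula[[2L]], data)
  sw <- sqrt(weights)
  resfun <- function(par)
    sw * (lhs - eval(rhs, c(as.list(data), as.list(par))))
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(unlist(st), lower = lower, upper = upper,
                         fn = resfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500)),
      error = function(e) { best_msg <<- conditionMessage(e); NULL })
    if (!is.null(out) && is.finite(out$deviance) &&
        out$deviance < best_rss) {
      best <- out
      best_rss <- out$deviance
    }
  }
  if (is.null(best))
    stop("fit-failure: ", best_msg)
  n <- length(lhs)
  p <- length(best$par)
  sigma2 <- best$deviance / max(n - p, 1)
  cv <- tryCatch(solve(best$hessian) * sigma2, error = function(e) {
    # pseudo-inverse along the identifiable directions
    eg <- eigen(best$hessian, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-12
    (eg$vectors[, keep, drop = FALSE] %*%
       diag(1 / eg$values[keep], sum(keep)) %*%
       t(eg$vectors[, keep, drop = FALSE])) * sigma2
  })
  dimnames(cv) <- list(names(best$par), names(best$par))
  structure(list(par = unlist(best$par), cov = cv,
                 resid = resfun(best$par) / sw),
            class = "lm_direct_fit")
}

#' @export
coef.lm_direct_fit <- function(object, ...) object$par

#' @export
vcov.lm_direct_fit <- function(object, ...) object$cov

#' @export
residuals.lm_direct_fit <- function(object, ...) object$resid

#' Fit the double-exponential decay of the trivial-lasso probability
#'
#' Fits `P(x) = Pinf + ca * exp(-alpha * x) + cb * exp(-beta * x)` by
#' weighted (inverse-variance) nonlinear least squares with multi-start
#' initialisation over rate combinations alpha in {0.3, 0.03} and beta in
#' {0.05, 0.005}; amplitudes start from the endpoint residuals and `Pinf`
#' from the largest-length mean.  The two fitted rates typically differ by
#' an order of magnitude, separating short- and long-chain regimes.
#'
#' @param x Varying length (loop length N or tail length t).
#' @param p Trivial-lasso probability per length.
#' @param se Binomial standard errors (zero SEs are floored by the caller;
#'   see [trivial_probability()]).
#' @param fixed_var Annotation: which of `"N"` or `"t"` was held fixed
#'   (`"none"` on the equal-length diagonal).
#' @return A `decay_fit`: list with `params` (Pinf, ca, alpha, cb, beta),
#'   `se` (parameter standard errors), `cov`, `fixed_var`, `fit`.
#' @export
fit_decay_1d <- function(x, p, se, fixed_var = "none") {
  stopifnot(length(x) >= 6L, length(p) == length(x),
            length(se) == length(x), all(se > 0))
  dat <- data.frame(x = x, p = p)
  w <- 1 / se^2
  p_inf0 <- p[which.max(x)]
  resid0 <- max(p[which.min(x)] - p_inf0, 1e-3)
  starts <- list()
  for (al in c(0.3, 0.03)) for (be in c(0.05, 0.005)) {
    starts[[length(starts) + 1L]] <-
      list(Pinf = p_inf0, ca = resid0 / 2, alpha = al, cb = resid0 / 2,
           beta = be)
  }
  # Pinf is a probability, and the law describes a monotone decay towards
  # the asymptote from above, so both amplitudes are non-negative; rates
  # above ~2 die within a single step.  Without these constraints the
  # five-parameter model is unidentified on short series (near-equal rates
  # with cancelling amplitudes can place the asymptote anywhere).
  fit <- fit_multistart(
    p ~ Pinf + ca * exp(-alpha * x) + cb * exp(-beta * x), dat, starts,
    weights = w, lower = c(0, 0, 1e-8, 0, 1e-8),
    upper = c(1, 2, 2, 2, 2))
  cf <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, 5, 5, dimnames = list(names(cf), names(cf))))
  structure(list(params = cf, se = sqrt(pmax(diag(cv), 0)), cov = cv,
                 fixed_var = fixed_var, fit = fit),
            class = "decay_fit")
}

#' Evaluate a fitted 1D decay law
#' @param fit A `decay_fit`.
#' @param x Lengths.
#' @return Fitted probabilities.
#' @export
predict_decay <- function(fit, x) {
  cf <- fit$params
  unname(cf["Pinf"] + cf["ca"] * exp(-cf["alpha"] * x) +
           cf["cb"] * exp(-cf["beta"] * x))
}

#' Fit the trivial-lasso probability surface over the (N, t) grid
#'
#' Fits `P(N, t) = Pinf + ca_t exp(-alpha_t t) + ca_N exp(-alpha_N N) +
#' cb_t exp(-beta_t t) + cb_N exp(-beta_N N)` (shared asymptote, a short-
#' and a long-range exponential per variable) by weighted least squares
#' over all grid cells, multi-start as in [fit_decay_1d()].
#'
#' @param table An `ensemble_table` or a data frame with columns `N`, `t`,
#'   `p`, `se`.
#' @return A `surface_fit`: list with `params` (Pinf, ca_t, alpha_t, ca_N,
#'   alpha_N, cb_t, beta_t, cb_N, beta_N), `se`, `cov`, `fit`.
#' @export
fit_probability_surface <- function(table) {
  dat <- if (inherits(table, "ensemble_table")) trivial_probability(table)
         else table
  stopifnot(all(c("N", "t", "p", "se") %in% names(dat)))
  if (length(unique(dat$N)) < 4L || length(unique(dat$t)) < 4L)
    stop("surface fit needs a grid with >= 4 distinct N and t values")
  w <- 1 / dat$se^2
  p_inf0 <- mean(dat$p[dat$N == max(dat$N) | dat$t == max(dat$t)])
  amp0 <- max(max(dat$p) - p_inf0, 1e-3) / 4
  starts <- list()
  # slightly asymmetric amplitude starts keep the initial Jacobian full
  # rank (identical twin exponentials make it singular)
  for (al in c(0.3, 0.1, 0.03)) for (be in c(0.05, 0.005)) {
    if (al == be) next
    starts[[length(starts) + 1L]] <-
      list(Pinf = p_inf0, ca_t = amp0, alpha_t = al, ca_N = 0.8 * amp0,
           alpha_N = 1.3 * al, cb_t = 0.6 * amp0, beta_t = be,
           cb_N = 0.5 * amp0, beta_N = 0.7 * be)
  }
  fit <- fit_multistart(
    p ~ Pinf + ca_t * exp(-alpha_t * t) + ca_N * exp(-alpha_N * N) +
      cb_t * exp(-beta_t * t) + cb_N * exp(-beta_N * N),
    dat, starts, weights = w,
    lower = c(0, -2, 1e-8, -2, 1e-8, -2, 1e-8, -2, 1e-8),
    upper = c(1, 2, 2, 2, 2, 2, 2, 2, 2))
  cf <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf))))
  structure(list(params = cf, se = sqrt(pmax(diag(cv), 0)), cov = cv,
                 fit = fit),
            class = "surface_fit")
}

#' Evaluate a fitted probability surface
#' @param fit A `surface_fit`.
#' @param N,t Loop and tail lengths (vectorised).
#' @return Trivial-lasso probabilities (not clamped).
#' @export
predict_surface <- function(fit, N, t) {
  cf <- fit$params
  unname(cf["Pinf"] + cf["ca_t"] * exp(-cf["alpha_t"] * t) +
           cf["ca_N"] * exp(-cf["alpha_N"] * N) +
           cf["cb_t"] * exp(-cf["beta_t"] * t) +
           cf["cb_N"] * exp(-cf["beta_N"] * N))
}

#' Domination number of a piercing spectrum
#'
#' The largest piercing count p such that, among non-trivial lassos, those
#' with at least p piercings are the strict majority:
#' `d = max(p) : P(n >= p | n > 0) > 1/2` (equality does not count).
#'
#' @param spectrum Either a data frame with columns `n_piercings` and
#'   `count`, or a named numeric vector (names = piercing counts).
#' @return A `domination_result`: list with `d` and `tail_prob` (data
#'   frame: p, P(n >= p | n > 0)).
#' @export
domination_number <- function(spectrum) {
  if (is.data.frame(spectrum)) {
    n <- spectrum$n_piercings
    cnt <- spectrum$count
  } else {
    n <- as.integer(names(spectrum))
    cnt <- as.numeric(spectrum)
  }
  keep <- n > 0
  n <- n[keep]
  cnt <- cnt[keep]
  if (length(n) == 0L || sum(cnt) == 0)
    stop("undefined-domination: no non-trivial lassos in the spectrum")
  total <- sum(cnt)
  ps <- seq_len(max(n))
  tail_prob <- vapply(ps, function(p) sum(cnt[n >= p]) / total, 0)
  d <- max(ps[tail_prob > 0.5])
  structure(list(d = d,
                 tail_prob = data.frame(p = ps, prob = tail_prob)),
            class = "domination_result")
}

#' Geometric model for the asymptotic piercing-count distribution
#'
#' Treats the tail drifting away from the loop as a success with
#' probability `p_success` (the asymptotic trivial-lasso probability) and
#' each piercing as a failure, giving `P(n) = p (1 - p)^n` for n >= 0
#' piercings (n = 0 is the trivial lasso).
#'
#' @param p_success Success probability in (0, 1).
#' @param n_max Largest piercing count to tabulate.
#' @return Data frame with `n` and `prob` (and the analytic tail mass
#'   beyond `n_max` in the `tail` attribute).
#' @export
geometric_piercing_model <- function(p_success, n_max = 20L) {
  if (!is.numeric(p_success) || length(p_success) != 1L ||
      is.na(p_success) || p_success <= 0 || p_success >= 1)
    stop("p_success must lie strictly inside (0, 1)")
  n <- 0:n_max
  out <- data.frame(n = n, prob = p_success * (1 - p_success)^n)
  attr(out, "tail") <- (1 - p_success)^(n_max + 1)
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("double-exponential decay fit (fixed:", x$fixed_var, ")\n")
  print(round(x$params, 5))
  invisible(x)
}

#' @export
print.domination_result <- function(x, ...) {
  cat("domination number d =", x$d, "\n")
  invisible(x)
}
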