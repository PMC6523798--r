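# Phantom-lasso generation: uniform equilateral polygons, random-walk tails,
# seeded reproducible ensembles.  All phantom chains use unit edge length;
# the analysis of these chains is scale-free.

#' Sample a uniform random equilateral closed polygon
#'
#' Draws a closed polygon with `k` unit edges from the uniform measure on
#' equilateral polygon space, using fan-diagonal (action-angle) coordinates:
#' the k-3 differences between neighbouring fan diagonals are sampled
#' uniformly from \[-1,1\] and sequences violating the triangle inequalities
#' of the fan triangles are rejected and redrawn; valid sequences are
#' completed with uniform dihedral angles about each diagonal.
#'
#' Randomness comes from R's global RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param k Number of edges (at least 3).
#' @return A `loop_conformation`: list with `vertices` (k x 3 matrix),
#'   `edge_length` (1), `n_edges`, and `attempts` (rejection-sampling draws
#'   used).
#' @export
#' @examples
#' set.seed(1)
#' loop <- sample_equilateral_polygon(20)
#' range(sqrt(rowSums((loop$vertices -
#'   loop$vertices[c(2:20, 1), ])^2)))  # all edges 1
sample_equilateral_polygon <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 3)
    stop("k must be a single integer >= 3")
  res <- cpp_sample_polygon(as.integer(k))
  structure(
    list(vertices = res$vertices, edge_length = 1.0,
         n_edges = as.integer(k), attempts = res$attempts),
    class = "loop_conformation")
}

#' Sample an equilateral random-walk tail
#'
#' A walk of `t` unit steps with isotropic random directions, starting at
#' `origin`.
#'
#' @param t Number of steps (>= 0).
#' @param origin Numeric length-3 start point.
#' @return Numeric (t+1) x 3 matrix of vertices (a 3D polyline).
#' @export
sample_random_walk_tail <- function(t, origin = c(0, 0, 0)) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single integer >= 0")
  t <- as.integer(t)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  if (t == 0L) return(matrix(origin, nrow = 1L, ncol = 3L))
  z <- runif(t, -1, 1)
  phi <- runif(t, 0, 2 * pi)
  r <- sqrt(pmax(1 - z^2, 0))
  steps <- cbind(r * cos(phi), r * sin(phi), z)
  pos <- rbind(c(0, 0, 0), cbind(cumsum(steps[, 1L]), cumsum(steps[, 2L]),
                                 cumsum(steps[, 3L])))
  sweep(pos, 2L, origin, "+")
}

#' Assemble a phantom lasso from a loop and freshly sampled tails
#'
#' The loop is translated so its first vertex sits at the origin; each tail
#' is an equilateral random walk started there.  With two tails both share
#' the anchor vertex (the bridge), mirroring a disulfide bridge joining both
#' termini at one point.
#'
#' @param loop A `loop_conformation`.
#' @param tail_lengths Integer vector of 0-2 tail lengths.
#' @return A `lasso_conformation`: list with `loop`, `tails` (list of
#'   polyline matrices), `anchor_indices`.
#' @export
build_lasso <- function(loop, tail_lengths = integer(0)) {
  stopifnot(inherits(loop, "loop_conformation"))
  if (length(tail_lengths) > 2L)
    stop("a lasso has at most 2 tails")
  v <- loop$vertices
  v <- sweep(v, 2L, v[1L, ], "-")
  loop$vertices <- v
  tails <- lapply(tail_lengths, sample_random_walk_tail,
                  origin = c(0, 0, 0))
  structure(
    list(loop = loop, tails = tails,
         anchor_indices = rep(1L, length(tails))),
    class = "lasso_conformation")
}

#' Ensemble specification for phantom lassos
#'
#' @param loop_lengths,tail_lengths Positive integer vectors; the ensemble
#'   covers their Cartesian product of (N, t) cells.
#' @param samples_per_cell Samples per (N, t) cell (>= 1).
#' @param master_seed Integer master seed; every (N, t, sample) triple gets
#'   its own child seed so cells are independently reproducible.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(loop_lengths, tail_lengths, samples_per_cell,
                          master_seed) {
  stopifnot(all(loop_lengths >= 3), all(tail_lengths >= 0),
            samples_per_cell >= 1, is.finite(master_seed))
  structure(
    list(loop_lengths = as.integer(loop_lengths),
         tail_lengths = as.integer(tail_lengths),
         samples_per_cell = as.integer(samples_per_cell),
         master_seed = as.integer(master_seed)),
    class = "ensemble_spec")
}

#' Deterministic child seed for one ensemble member
#'
#' A multiplicative-congruential hash of (master seed, N, t, sample index),
#' kept below 2^31 so it is a valid [set.seed()] argument.
#'
#' @param master_seed,N,t,index Integers.
#' @return A single integer seed.
#' @export
child_seed <- function(master_seed, N, t, index) {
  h <- as.double(master_seed %% 2147483563)
  for (v in c(N, t, index)) {
    h <- (h * 69069 + as.double(v) + 1) %% 2147483563
  }
  as.integer(h)
}

#' Generate a phantom-lasso ensemble
#'
#' Iterates the (N, t) cells of `spec`; for each sample the child seed is
#' set, a loop and one tail are drawn, and the resulting lasso is either
#' collected or passed to `callback(cell, lasso)`.
#'
#' @param spec An [ensemble_spec()].
#' @param callback Optional `function(cell, lasso)`; when supplied the
#'   ensemble is streamed and only the callback results are returned.
#' @return A list of `list(cell, lasso)` entries, or the list of callback
#'   results.
#' @export
generate_ensemble <- function(spec, callback = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  out <- vector("list",
                length(spec$loop_lengths) * length(spec$tail_lengths) *
                  spec$samples_per_cell)
  pos <- 0L
  for (N in spec$loop_lengths) {
    for (t in spec$tail_lengths) {
      for (s in seq_len(spec$samples_per_cell)) {
        set.seed(child_seed(spec$master_seed, N, t, s))
        lasso <- build_lasso(sample_equilateral_polygon(N), t)
        cell <- list(N = N, t = t, sample = s)
        pos <- pos + 1L
        out[[pos]] <- if (is.null(callback)) list(cell = cell, lasso = lasso)
                      else callback(cell, lasso)
      }
    }
  }
  out
}

#' @export
print.loop_conformation <- function(x, ...) {
  cat(sprintf("equilateral loop: %d edges of length %g\n",
              x$n_edges, x$edge_length))
  invisible(x)
}

#' @export
print.lasso_conformation <- function(x, ...) {
  cat(sprintf("lasso: loop of %d edges, %d tail(s) of length %s\n",
              x$loop$n_edges, length(x$tails),
              paste(vapply(x$tails, nrow, 1L) - 1L, collapse = ", ")))
  invisible(x)
}
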