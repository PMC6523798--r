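# Threading classification: span a near-minimal triangulated surface on the
# loop, count signed transversal tail piercings, assign the lasso class.

#' Span a near-minimal triangulated surface on a closed loop
#'
#' The initial surface is a fan of triangles from the loop centroid.  It is
#' refined by conforming edge-midpoint subdivision until every interior edge
#' is at most `target_edge`, then relaxed by sweeps that move interior
#' vertices only (cotangent-Laplacian updates with a monotone
#' area-gradient-descent fallback), so the surface area never increases
#' across sweeps.  Relaxation stops when the relative area change per sweep
#' drops below `tol` or after `max_sweeps` sweeps.
#'
#' The loop may self-intersect (phantom chains do); the spanning still
#' proceeds.  A numerically collinear loop raises a degenerate-surface
#' error.
#'
#' @param loop A `loop_conformation` or an n x 3 matrix of closed-loop
#'   vertices (closing edge implied).
#' @param target_edge Refinement target edge length; defaults to the mean
#'   boundary edge length.
#' @param tol Relative area-change stopping tolerance per sweep.
#' @param max_sweeps Sweep cap.
#' @return A `tri_surface`: list with `vertices`, `triangles` (1-based
#'   index triples, consistently oriented), `n_boundary` (the first
#'   `n_boundary` vertices are the fixed loop), `area`, `area_initial` (the
#'   centroid-fan area), `sweeps`, `mean_edge`.
#' @export
span_minimal_surface <- function(loop, target_edge = NULL, tol = 1e-4,
                                 max_sweeps = 200L) {
  v <- if (inherits(loop, "loop_conformation")) loop$vertices else
    as.matrix(loop)
  stopifnot(is.matrix(v), ncol(v) == 3L, nrow(v) >= 3L)
  if (!all(is.finite(v))) stop("non-finite loop coordinates")
  res <- cpp_span_surface(v, if (is.null(target_edge)) -1 else target_edge,
                          tol, as.integer(max_sweeps))
  structure(res, class = "tri_surface")
}

#' Count signed transversal piercings of a tail through a spanned surface
#'
#' Every transversal intersection of a tail segment with the open surface
#' interior is recorded with its orientation sign (+1 along the consistent
#' surface normal, -1 against it).  Intersections within a geometric
#' epsilon of the boundary curve or of the anchor vertex are excluded;
#' hits that land exactly on a mesh edge or vertex are resolved by a
#' deterministic retry with the tail shifted by a fixed tiny vector.
#'
#' @param surface A `tri_surface`.
#' @param tail Numeric m x 3 polyline matrix, anchored on the surface
#'   boundary.
#' @param anchor_index Index of the boundary loop vertex the tail is
#'   anchored at (default 1).
#' @return A `piercing_record`: list with `crossings` (data.frame: segment,
#'   triangle, sign, x, y, z, ordered along the tail), `n_total`,
#'   `signed_sum`.
#' @export
count_piercings <- function(surface, tail, anchor_index = 1L) {
  stopifnot(inherits(surface, "tri_surface"))
  tail <- as.matrix(tail)
  stopifnot(ncol(tail) == 3L)
  if (!all(is.finite(tail))) stop("non-finite tail coordinates")
  anchor <- surface$vertices[anchor_index, ]
  res <- cpp_count_piercings(surface$vertices, surface$triangles,
                             surface$n_boundary, tail, anchor,
                             surface$mean_edge)
  cr <- res$crossings
  crossings <- data.frame(segment = as.integer(cr[, 1L]),
                          triangle = as.integer(cr[, 2L]),
                          sign = as.integer(cr[, 3L]),
                          x = cr[, 4L], y = cr[, 5L], z = cr[, 6L])
  structure(list(crossings = crossings,
                 n_total = nrow(crossings),
                 signed_sum = sum(crossings$sign)),
            class = "piercing_record")
}

#' Classify the threading topology of a lasso
#'
#' Spans a near-minimal surface on the loop and counts transversal
#' piercings by each tail.  The label is `L0` when no tail pierces, `L<n>`
#' for a single piercing tail with `n` total crossings (piercing directions
#' merged), and `LL_<i>,<j>` when both tails pierce.
#'
#' @param lasso A `lasso_conformation`.
#' @param target_edge,tol,max_sweeps Passed to [span_minimal_surface()].
#' @return List with `label`, `n_piercings_total`, `records` (one
#'   `piercing_record` per tail) and the spanned `surface`.
#' @export
classify_lasso <- function(lasso, target_edge = NULL, tol = 1e-4,
                           max_sweeps = 200L) {
  stopifnot(inherits(lasso, "lasso_conformation"))
  surface <- span_minimal_surface(lasso$loop, target_edge, tol, max_sweeps)
  records <- vector("list", length(lasso$tails))
  counts <- integer(length(lasso$tails))
  for (i in seq_along(lasso$tails)) {
    records[[i]] <- count_piercings(surface, lasso$tails[[i]],
                                    lasso$anchor_indices[i])
    counts[i] <- records[[i]]$n_total
  }
  label <- lasso_class_label(counts)
  list(label = label, n_piercings_total = sum(counts),
       records = records, surface = surface)
}

#' Build the lasso class string from per-tail piercing counts
#'
#' @param counts Integer vector (one entry per tail) of total crossings.
#' @return Class string: `"L0"`, `"L<n>"`, or `"LL_<i>,<j>"`.
#' @export
lasso_class_label <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) == 0L || all(counts == 0L)) return("L0")
  if (length(counts) == 2L && all(counts > 0L))
    return(sprintf("LL_%d,%d", counts[1L], counts[2L]))
  sprintf("L%d", sum(counts))
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf(
    "spanned surface: %d vertices, %d triangles, area %.4f (fan %.4f)\n",
    nrow(x$vertices), nrow(x$triangles), x$area, x$area_initial))
  invisible(x)
}

#' @export
print.piercing_record <- function(x, ...) {
  cat(sprintf("piercings: %d total, signed sum %+d\n", x$n_total,
              x$signed_sum))
  invisible(x)
}
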