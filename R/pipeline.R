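# Orchestration: streamed generate -> classify -> tabulate -> fit for the
# phantom track, simulate -> shapes -> fit for the simulation track, plus
# plain-text serialisation (extended XYZ, CSV/JSON manifests).

#' Generate and classify a phantom-lasso ensemble
#'
#' Streams the ensemble cell by cell: for every sample the child seed is
#' set, a loop and a single tail are drawn, the loop surface is spanned and
#' the tail piercings counted.  Only the per-sample class and piercing
#' count are kept, so memory stays flat in the sample count.
#'
#' @param loop_lengths,tail_lengths Cell grid (crossed); pass equal vectors
#'   with `diagonal = TRUE` to classify only the equal-length diagonal.
#' @param samples_per_cell Samples per (N, t) cell.
#' @param master_seed Master seed; see [child_seed()].
#' @param diagonal Classify only cells with N = t.
#' @param tol,max_sweeps Surface relaxation controls (see
#'   [span_minimal_surface()]).
#' @return Data frame: N, t, sample, n_piercings, signed_sum, class.
#' @export
run_phantom_pipeline <- function(loop_lengths, tail_lengths = loop_lengths,
                                 samples_per_cell = 100L, master_seed = 1L,
                                 diagonal = FALSE, tol = 1e-4,
                                 max_sweeps = 200L) {
  cells <- expand.grid(N = as.integer(loop_lengths),
                       t = as.integer(tail_lengths))
  if (diagonal) cells <- cells[cells$N == cells$t, , drop = FALSE]
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    N <- cells$N[ci]
    t <- cells$t[ci]
    n_p <- integer(samples_per_cell)
    s_s <- integer(samples_per_cell)
    for (s in seq_len(samples_per_cell)) {
      set.seed(child_seed(master_seed, N, t, s))
      lasso <- build_lasso(sample_equilateral_polygon(N), t)
      cl <- classify_lasso(lasso, tol = tol, max_sweeps = max_sweeps)
      n_p[s] <- cl$n_piercings_total
      s_s[s] <- cl$records[[1L]]$signed_sum
    }
    res[[ci]] <- data.frame(N = N, t = t, sample = seq_len(samples_per_cell),
                            n_piercings = n_p, signed_sum = s_s,
                            class = ifelse(n_p == 0L, "L0",
                                           sprintf("L%d", n_p)))
  }
  do.call(rbind, res)
}

#' Simulate a sweep of loop lengths and tabulate shape descriptors
#'
#' For each loop length: run the Monte Carlo, remove the chord-correlation
#' burn-in, thin to decorrelated frames and collect the mean shape
#' descriptors.
#'
#' @param N_values Loop lengths.
#' @param w Thread thickness factor.
#' @param T Temperature (reduced units).
#' @param sweeps,stride,tune_sweeps Per-run Monte Carlo controls (see
#'   [sim_config()]).
#' @param master_seed Seed; each N gets child seed `child_seed(seed, N, w, 0)`.
#' @param min_frames Require at least this many decorrelated frames.
#' @param burn_in Optional explicit burn-in (recorded frames) overriding
#'   the chord-correlation rule; useful for tightly threaded small loops
#'   whose chord correlation decays very slowly to the 0.1 mark.
#' @return Data frame (one row per N) as returned by [shape_table()].
#' @export
run_shape_sweep <- function(N_values, w = 0L, T = 100, sweeps = 4000L,
                            stride = 2L, tune_sweeps = 200L,
                            master_seed = 1L, min_frames = 200L,
                            burn_in = NULL) {
  rows <- lapply(N_values, function(N) {
    cfg <- sim_config(N = N, w = w, T = T, sweeps = sweeps, stride = stride,
                      tune_sweeps = tune_sweeps,
                      seed = child_seed(master_seed, N, w, 0L))
    traj <- run_simulation(cfg)
    traj <- discard_burnin(traj, burn_in = burn_in)
    tab <- shape_table(traj)
    if (tab$n_frames < min_frames)
      warning(sprintf(
        "N = %d: only %d decorrelated frames (< %d); lengthen the run",
        N, tab$n_frames, min_frames))
    tab
  })
  do.call(rbind, rows)
}

#' Write conformations as an extended XYZ file
#'
#' One frame per conformation; the comment line carries `key=value` pairs
#' (loop length, tail length, seed, tail offsets).
#'
#' @param conformations List of `lasso_conformation` objects or coordinate
#'   matrices.
#' @param file Output path.
#' @param comments Optional character vector of per-frame comment lines.
#' @export
write_xyz <- function(conformations, file, comments = NULL) {
  con <- base::file(file, "w")
  on.exit(close(con))
  for (i in seq_along(conformations)) {
    cf <- conformations[[i]]
    coords <- if (inherits(cf, "lasso_conformation")) {
      tails <- do.call(rbind, cf$tails)
      rbind(cf$loop$vertices, tails)
    } else as.matrix(cf)
    cmt <- if (!is.null(comments)) comments[i] else {
      if (inherits(cf, "lasso_conformation"))
        sprintf("N=%d tails=%s", cf$loop$n_edges,
                paste(vapply(cf$tails, nrow, 1L) - 1L, collapse = ","))
      else sprintf("frame=%d", i)
    }
    writeLines(sprintf("%d", nrow(coords)), con)
    writeLines(cmt, con)
    writeLines(sprintf("C %.9f %.9f %.9f", coords[, 1L], coords[, 2L],
                       coords[, 3L]), con)
  }
  invisible(file)
}

#' Read an extended XYZ file
#' @param file Path.
#' @return List of frames: each a list with `coords` (matrix) and
#'   `comment`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cmt <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    coords <- matrix(as.numeric(parts[, 2:4]), ncol = 3L)
    out[[length(out) + 1L]] <- list(coords = coords, comment = cmt)
    i <- i + 2L + n
  }
  out
}

#' Run the full phantom + simulation pipeline and write a manifest
#'
#' Executes the phantom track (generate, classify, tabulate, decay fit)
#' and/or the simulation track (simulate, shapes, scaling fits) and writes
#' all tables (CSV) plus a JSON manifest with the resolved configuration
#' and output hashes next to them.
#'
#' @param out_dir Output directory (created if missing).
#' @param phantom List of arguments for [run_phantom_pipeline()] or `NULL`
#'   to skip the phantom track.
#' @param shapes List of arguments for [run_shape_sweep()] or `NULL` to
#'   skip the simulation track.
#' @param master_seed Seed recorded in (and applied through) both tracks.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, phantom = list(loop_lengths = c(10, 20)),
                         shapes = NULL, master_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("lassopoly")),
                   master_seed = master_seed, created = "",
                   outputs = list())
  add_output <- function(name, path) {
    manifest$outputs[[name]] <<- list(
      file = basename(path),
      sha = unname(tools::md5sum(path)))
  }
  if (!is.null(phantom)) {
    if (is.null(phantom$loop_lengths))
      stop("pipeline config is missing the required field 'loop_lengths'")
    phantom$master_seed <- master_seed
    classified <- do.call(run_phantom_pipeline, phantom)
    path <- file.path(out_dir, "phantom_classified.csv")
    write.csv(classified, path, row.names = FALSE)
    add_output("phantom_classified", path)
    tab <- tabulate_ensemble(classified)
    path <- file.path(out_dir, "phantom_classes.csv")
    write.csv(tab$classes, path, row.names = FALSE)
    add_output("phantom_classes", path)
  }
  if (!is.null(shapes)) {
    shapes$master_seed <- master_seed
    st <- do.call(run_shape_sweep, shapes)
    path <- file.path(out_dir, "shape_table.csv")
    write.csv(st, path, row.names = FALSE)
    add_output("shape_table", path)
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
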