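# Synthetic protein structures with a disulfide-closed loop, written as
# plain PDB text.  These are geometric constructions (not real proteins)
# used to exercise the protein bridge on known ground truth.

# strict PDB ATOM column layout (name 13-16, resName 18-20, chain 22,
# resSeq 23-26, coordinates 31-54)
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, paste0(" ", name), resname, chain, resno,
          xyz[1L], xyz[2L], xyz[3L])
}

#' Write a synthetic lasso protein structure as a PDB file
#'
#' Builds an idealised alpha-carbon trace (3.8 Angstrom spacing): a short
#' N-terminal tail, a planar circular loop closed by a CYS-CYS bridge, and
#' a C-terminal tail that either threads once through the loop plane
#' (`threading = "single"`), passes through and back (`"double"`), stays
#' clear of the loop (`"none"`), or threads with both tails
#' (`"both"`).  The bridge is emitted as an SSBOND record and, when
#' `sg_atoms = TRUE`, also as a pair of SG atoms 2.0 Angstrom apart.
#'
#' @param file Output path.
#' @param loop_size Number of loop residues.
#' @param t1,t2 Tail lengths in residues (t1 = N-terminal).
#' @param threading One of `"single"`, `"double"`, `"none"`, `"both"`.
#' @param ssbond Emit the SSBOND header record.
#' @param sg_atoms Emit SG atoms for the bridge cysteines.
#' @param chain Chain identifier.
#' @return The path, invisibly; ground truth is attached as the
#'   `"truth"` attribute (expected class label).
#' @export
synthetic_lasso_pdb <- function(file, loop_size = 24L, t1 = 4L, t2 = 10L,
                                threading = c("single", "double", "none",
                                              "both"),
                                ssbond = TRUE, sg_atoms = FALSE,
                                chain = "A") {
  threading <- match.arg(threading)
  step <- 3.8
  R <- loop_size * step / (2 * pi)     # circle with ~step-spaced residues
  th <- 2 * pi * (seq_len(loop_size) - 1) / loop_size
  loop <- cbind(R * cos(th), R * sin(th), 0)

  # resample a waypoint polyline at equal `step` arc-length spacing so the
  # tails look like a CA trace; after the last waypoint the path continues
  # along `drift_dir` indefinitely
  walk_path <- function(start, waypoints, drift_dir, n) {
    P <- rbind(start, do.call(rbind, waypoints))
    u <- drift_dir / sqrt(sum(drift_dir^2))
    P <- rbind(P, P[nrow(P), ] + u * step * (n + 5))
    seg <- diff(P)
    L <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(L))
    t(vapply(step * seq_len(n), function(s) {
      i <- min(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
      P[i, ] + (s - cum[i]) / L[i] * seg[i, ]
    }, numeric(3L)))
  }

  # N-terminal tail, stored in ascending residue order (N-terminus first)
  tail1 <- NULL
  if (t1 > 0) {
    if (threading == "both") {
      # rise above the plane, pierce once downward through the interior,
      # then drift away below the loop
      wp <- list(loop[1L, ] + c(0, 0, step),
                 c(0.25 * R, 0.1 * R, step),
                 c(0.2 * R, 0.1 * R, -step))
      pts <- walk_path(loop[1L, ], wp, c(0, 0, -1), t1)
    } else {
      # walk radially away from the loop in its plane
      dir_out <- c(cos(-pi / loop_size), sin(-pi / loop_size), 0)
      pts <- walk_path(loop[1L, ], list(), dir_out, t1)
    }
    tail1 <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  }

  last <- loop[loop_size, ]
  tail2 <- NULL
  if (t2 > 0) {
    if (threading %in% c("single", "double", "both")) {
      # approach the loop centre above the plane, then pierce downward
      wp <- list(last + c(0, 0, step), c(0.3 * R, 0, step),
                 c(0.25 * R, 0, -step))
      if (threading == "double")
        wp <- c(wp, list(c(-0.25 * R, 0, -step), c(-0.3 * R, 0, step)))
      drift_dir <- c(0, 0, if (threading == "double") 1 else -1)
    } else {
      # stay clear of the loop: drift radially outward, slightly off-plane
      wp <- list(last + c(step, 0, 0.2 * step))
      drift_dir <- c(1, 0, 0.05)
    }
    tail2 <- walk_path(last, wp, drift_dir, t2)
  }

  ca <- rbind(tail1, loop, tail2)
  n <- nrow(ca)
  res_loop <- (t1 + 1L):(t1 + loop_size)
  b1 <- t1 + 1L
  b2 <- t1 + loop_size

  lines <- character(0)
  lines <- c(lines, "HEADER    SYNTHETIC LASSO FIXTURE")
  lines <- c(lines,
             "REMARK    synthetic geometric construction, not a real protein")
  if (ssbond)
    lines <- c(lines, sprintf(
      "SSBOND   1 CYS %s %4d    CYS %s %4d", chain, b1, chain, b2))
  serial <- 0L
  for (i in seq_len(n)) {
    resname <- if (i %in% c(b1, b2)) "CYS" else "GLY"
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(serial, "CA", resname, chain, i,
                                    ca[i, ]))
    if (sg_atoms && i %in% c(b1, b2)) {
      serial <- serial + 1L
      # place the two SG atoms 2.0 A apart midway between the bridge CAs
      mid <- (ca[b1, ] + ca[b2, ]) / 2
      off <- if (i == b1) -1 else 1
      sg <- mid + c(0, off * 1.0, 0)
      lines <- c(lines, pdb_atom_line(serial, "SG", resname, chain, i, sg))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, file)
  truth <- switch(threading, single = "L1", double = "L2", none = "L0",
                  both = "LL_1,1")
  invisible(structure(file, truth = truth))
}
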