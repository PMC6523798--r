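# Bridge to protein structures: extract covalently closed backbone loops
# and their tails from PDB files, classify the lasso type with the same
# minimal-surface machinery, and score threading probabilities against the
# fitted phantom-polymer surface.

#' Read an alpha-carbon chain trace and its disulfide bridges from a PDB file
#'
#' Coordinates are converted to nm (PDB files are in Angstrom).  Disulfide
#' bridges are taken from SSBOND records; when sulfur atoms are present,
#' CYS SG-SG pairs closer than `sg_cutoff` Angstrom are additionally
#' detected (SSBOND records take precedence; duplicates are merged).
#' Residues without an alpha carbon are dropped with a warning, and
#' numbering gaps larger than 2 residues are recorded as a gap warning.
#'
#' @param file Path to a PDB-format file.
#' @param chain Chain identifier (default: first chain in the file).
#' @param sg_cutoff Geometric SG-SG detection threshold in Angstrom.
#' @return A `protein_chain`: list with `chain`, `resno`, `ca` (n x 3
#'   matrix, nm), `bridges` (two-column matrix of bridged residue
#'   numbers), `gaps`.
#' @export
read_chain <- function(file, chain = NULL, sg_cutoff = 2.5) {
  pdb <- bio3d::read.pdb(file)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1L]
  sel <- atoms$chain == chain & atoms$elety == "CA" &
    atoms$type %in% c("ATOM", "HETATM")
  if (!any(sel)) stop(sprintf("not-found: no chain '%s' with CA atoms",
                              chain))
  ca <- atoms[sel, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  drop <- !is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)
  if (any(drop)) {
    warning(sprintf("dropping %d residue(s) with missing alpha carbons",
                    sum(drop)))
    ca <- ca[!drop, , drop = FALSE]
  }
  gaps <- which(diff(ca$resno) > 2L)
  if (length(gaps))
    warning(sprintf("chain gap(s) larger than 2 residues after residue(s) %s",
                    paste(ca$resno[gaps], collapse = ", ")))

  bridges <- matrix(integer(0), ncol = 2L)
  # SSBOND records (bio3d does not expose them; parse the header lines)
  hdr <- grep("^SSBOND", readLines(file, warn = FALSE), value = TRUE)
  for (ln in hdr) {
    ch1 <- substr(ln, 16, 16)
    ch2 <- substr(ln, 30, 30)
    r1 <- suppressWarnings(as.integer(substr(ln, 18, 21)))
    r2 <- suppressWarnings(as.integer(substr(ln, 32, 35)))
    if (identical(ch1, chain) && identical(ch2, chain) &&
        !is.na(r1) && !is.na(r2))
      bridges <- rbind(bridges, sort(c(r1, r2)))
  }
  # geometric SG-SG detection
  sg <- atoms[atoms$chain == chain & atoms$elety == "SG" &
                atoms$resid == "CYS", , drop = FALSE]
  if (nrow(sg) >= 2L) {
    for (i in seq_len(nrow(sg) - 1L)) for (j in (i + 1L):nrow(sg)) {
      d <- sqrt(sum((c(sg$x[i], sg$y[i], sg$z[i]) -
                       c(sg$x[j], sg$y[j], sg$z[j]))^2))
      if (d <= sg_cutoff)
        bridges <- rbind(bridges, sort(c(sg$resno[i], sg$resno[j])))
    }
  }
  bridges <- unique(bridges)
  bridges <- bridges[bridges[, 1L] != bridges[, 2L], , drop = FALSE]
  structure(list(chain = chain, resno = ca$resno,
                 ca = cbind(ca$x, ca$y, ca$z) / 10,
                 bridges = bridges, gaps = ca$resno[gaps]),
            class = "protein_chain")
}

#' Extract bridge-closed loops and their tails from a chain
#'
#' For each bridge (i, j) the loop is the alpha-carbon stretch between the
#' bridged residues inclusive (closed by the bridge edge); the tails are
#' the N-terminal segment before the first bridged residue and the
#' C-terminal segment after the second, so loop and tails partition the
#' chain: N + t1 + t2 = chain length.
#'
#' @param chain A `protein_chain`.
#' @param bridges Optional explicit two-column matrix of bridged residue
#'   numbers (e.g., for non-disulfide covalent bridges), overriding the
#'   detected ones.
#' @return List of `bridge_loop` objects: `loop` (M x 3 matrix, nm), `N`
#'   (loop residues), `t1`, `t2` (tail residue counts), `tail1`, `tail2`
#'   (polylines walking outward from the bridge, including the anchor
#'   residue), `bridge` (residue-number pair).
#' @export
extract_lassos <- function(chain, bridges = NULL) {
  stopifnot(inherits(chain, "protein_chain"))
  br <- if (is.null(bridges)) chain$bridges else
    t(apply(as.matrix(bridges), 1L, sort))
  if (is.null(br) || nrow(br) == 0L)
    stop("no bridges: chain has no covalently closed loop")
  out <- vector("list", nrow(br))
  for (k in seq_len(nrow(br))) {
    i <- match(br[k, 1L], chain$resno)
    j <- match(br[k, 2L], chain$resno)
    if (is.na(i) || is.na(j))
      stop(sprintf("bridge residue %d or %d not present in the CA trace",
                   br[k, 1L], br[k, 2L]))
    n <- nrow(chain$ca)
    loop <- chain$ca[i:j, , drop = FALSE]
    # tails walk outward from the bridge residues (anchor included)
    tail1 <- if (i > 1L) chain$ca[i:1L, , drop = FALSE] else NULL
    tail2 <- if (j < n) chain$ca[j:n, , drop = FALSE] else NULL
    out[[k]] <- structure(
      list(loop = loop, N = j - i + 1L, t1 = i - 1L, t2 = n - j,
           tail1 = tail1, tail2 = tail2, bridge = br[k, ]),
      class = "bridge_loop")
  }
  out
}

#' Classify the lasso type of a protein bridge loop
#'
#' Spans a near-minimal surface on the loop (closed by the bridge edge)
#' and counts transversal piercings by each terminal tail.
#'
#' @param bl A `bridge_loop`.
#' @param ... Passed to [span_minimal_surface()].
#' @return List with `label`, `n_piercings_total`, per-tail `records`.
#' @export
classify_protein_lasso <- function(bl, ...) {
  stopifnot(inherits(bl, "bridge_loop"))
  surface <- span_minimal_surface(bl$loop, ...)
  nb <- surface$n_boundary
  tails <- list()
  anchors <- integer(0)
  if (!is.null(bl$tail1)) {
    tails <- c(tails, list(bl$tail1))
    anchors <- c(anchors, 1L)       # loop vertex 1 = first bridged residue
  }
  if (!is.null(bl$tail2)) {
    tails <- c(tails, list(bl$tail2))
    anchors <- c(anchors, nb)       # loop vertex N = second bridged residue
  }
  records <- vector("list", length(tails))
  counts <- integer(length(tails))
  for (q in seq_along(tails)) {
    records[[q]] <- count_piercings(surface, tails[[q]], anchors[q])
    counts[q] <- records[[q]]$n_total
  }
  list(label = lasso_class_label(counts), n_piercings_total = sum(counts),
       records = records)
}

#' Model threading probability of a bridge loop
#'
#' Per tail i, the probability of at least one piercing is
#' `p_i = 1 - P(N, t_i)` from the fitted trivial-lasso surface, clamped to
#' \[0, 1\]; the loop-level probability of at least one threading combines
#' the tails by inclusion-exclusion under independence:
#' `P(>=1) = 1 - prod(1 - p_i)`.  The probability that a tail reaches at
#' least `n` piercings applies the geometric multi-piercing model with
#' success parameter `P_inf`: `p_i * (1 - P_inf)^(n-1)`.
#'
#' @param bl A `bridge_loop`.
#' @param surface_fit A `surface_fit` from [fit_probability_surface()].
#' @param n_pierce Piercing count for the multi-piercing adjustment
#'   (default 1 = at least one threading).
#' @return A `threading_estimate`: list with per-tail `p_tail`,
#'   `p_any` (inclusion-exclusion across tails), `p_adjusted` (>=
#'   `n_pierce` piercings).
#' @export
threading_probability <- function(bl, surface_fit, n_pierce = 1L) {
  stopifnot(inherits(bl, "bridge_loop"))
  if (!inherits(surface_fit, "surface_fit"))
    stop("configuration error: fitted probability surface required")
  p_inf <- unname(surface_fit$params["Pinf"])
  ts <- c(bl$t1, bl$t2)
  p_tail <- vapply(ts, function(tl) {
    if (tl <= 0) return(0)
    min(max(1 - predict_surface(surface_fit, bl$N, tl), 0), 1)
  }, 0)
  p_any <- 1 - prod(1 - p_tail)
  p_adj <- if (n_pierce <= 1L) p_any else {
    padj_tail <- p_tail * (1 - p_inf)^(n_pierce - 1L)
    1 - prod(1 - padj_tail)
  }
  structure(list(p_tail = p_tail, p_any = p_any, p_adjusted = p_adj,
                 n_pierce = as.integer(n_pierce)),
            class = "threading_estimate")
}

#' Combine loop-level threading probabilities for a chain
#'
#' Inclusion-exclusion across loops under independence: the probability
#' that at least one loop of the chain is threaded.
#'
#' @param estimates List of `threading_estimate` objects (one per loop).
#' @return Scalar probability.
#' @export
chain_threading_probability <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  1 - prod(vapply(estimates, function(e) 1 - e$p_any, 0))
}

#' Select candidate functional lassos
#'
#' Loops that are observed non-trivial yet have very low model threading
#' probability: the threading must then be stabilised by something beyond
#' chain entropy.
#'
#' @param estimates Data frame with columns `label` (observed class) and
#'   `p_model` (model probability of the observed threading).
#' @param threshold Selection threshold on the model probability.
#' @return The selected rows of `estimates`.
#' @export
select_candidates <- function(estimates, threshold = 0.2) {
  stopifnot(all(c("label", "p_model") %in% names(estimates)))
  sel <- estimates$label != "L0" & estimates$p_model < threshold
  estimates[sel, , drop = FALSE]
}

#' Expected versus observed non-trivial lasso counts per chain length
#'
#' Expected count per length bin is the sum of the per-chain model
#' probabilities of at least one threading; observed is the count of
#' chains classified non-trivial.  Optional moving-average smoothing over
#' bins.
#'
#' @param chains Data frame with columns `length`, `p_any`, `label`.
#' @param bin_width Chain-length bin width (residues).
#' @param smooth_window Odd moving-average window in bins (1 = none).
#' @return Data frame with `bin_mid`, `n_chains`, `expected`, `observed`
#'   (plus smoothed columns when requested); empty bins are omitted.
#' @export
expected_vs_observed <- function(chains, bin_width = 50, smooth_window = 1L) {
  stopifnot(all(c("length", "p_any", "label") %in% names(chains)))
  bin <- floor(chains$length / bin_width)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(chains)), bin),
    function(idx) data.frame(
      bin_mid = (bin[idx[1L]] + 0.5) * bin_width,
      n_chains = length(idx),
      expected = sum(chains$p_any[idx]),
      observed = sum(chains$label[idx] != "L0"))))
  agg <- agg[order(agg$bin_mid), , drop = FALSE]
  rownames(agg) <- NULL
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    if (k %% 2L == 0L) k <- k + 1L
    ma <- function(v) as.numeric(stats::filter(v, rep(1 / k, k),
                                               sides = 2L))
    agg$expected_smooth <- ma(agg$expected)
    agg$observed_smooth <- ma(agg$observed)
  }
  agg
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("protein chain %s: %d CA residues, %d bridge(s)\n",
              x$chain, nrow(x$ca), nrow(x$bridges)))
  invisible(x)
}

#' @export
print.bridge_loop <- function(x, ...) {
  cat(sprintf("bridge loop %d-%d: N = %d, tails t1 = %d, t2 = %d\n",
              x$bridge[1L], x$bridge[2L], x$N, x$t1, x$t2))
  invisible(x)
}
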