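# Independent oracles used by the tests.  Each re-derives a quantity by a
# route different from the package implementation.

# Brute-force acceptance oracle for the polygon sampler: draw the k-3
# diagonal differences directly and test the fan triangle inequalities,
# without any reconstruction.
oracle_diagonal_acceptance <- function(k, n_draws) {
  ok <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    d <- 1
    valid <- TRUE
    for (j in seq_len(k - 3)) {
      nxt <- d[length(d)] + runif(1, -1, 1)
      if (nxt < 0 || nxt + d[length(d)] < 1) { valid <- FALSE; break }
      d <- c(d, nxt)
    }
    if (valid) {
      last <- d[length(d)]
      if (abs(1 - last) > 1) valid <- FALSE
    }
    ok[i] <- valid
  }
  mean(ok)
}

# Second, independent sampler of uniform equilateral polygons: the
# polygonal-fold Markov chain (rotate a random sub-arc about the chord
# through two random vertices by a uniform angle), which preserves the
# uniform measure on equilateral polygon space.
oracle_fold_mcmc_rg2 <- function(N, n_moves, sample_every = 10L) {
  th <- 2 * pi * (seq_len(N) - 1) / N
  R <- 1 / (2 * sin(pi / N))
  v <- cbind(R * cos(th), R * sin(th), 0)
  rg2 <- function(x) mean(rowSums(sweep(x, 2, colMeans(x))^2))
  out <- numeric(0)
  for (m in seq_len(n_moves)) {
    ij <- sort(sample.int(N, 2))
    i <- ij[1]; j <- ij[2]
    if (j - i < 2 || j - i > N - 2) next
    axis <- v[j, ] - v[i, ]
    an <- sqrt(sum(axis^2))
    if (an < 1e-12) next
    axis <- axis / an
    th1 <- runif(1, 0, 2 * pi)
    ct <- cos(th1); st <- sin(th1)
    for (b in (i + 1):(j - 1)) {
      w <- v[b, ] - v[i, ]
      ad <- sum(axis * w)
      cx <- c(axis[2] * w[3] - axis[3] * w[2],
              axis[3] * w[1] - axis[1] * w[3],
              axis[1] * w[2] - axis[2] * w[1])
      v[b, ] <- v[i, ] + w * ct + cx * st + axis * ad * (1 - ct)
    }
    if (m %% sample_every == 0) out <- c(out, rg2(v))
  }
  out
}

# direct double-loop radius of gyration
oracle_rg_bruteforce <- function(coords) {
  n <- nrow(coords)
  c0 <- colMeans(coords)
  s <- 0
  for (i in seq_len(n)) s <- s + sum((coords[i, ] - c0)^2)
  sqrt(s / n)
}

# gyration-tensor eigenvalues via the characteristic cubic's roots
oracle_gyration_eigenvalues <- function(coords) {
  x <- sweep(coords, 2, colMeans(coords))
  S <- crossprod(x) / nrow(x)
  cp <- c(-det(S),
          S[1, 1] * S[2, 2] + S[1, 1] * S[3, 3] + S[2, 2] * S[3, 3] -
            S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2,
          -(S[1, 1] + S[2, 2] + S[3, 3]),
          1)
  r <- sort(Re(polyroot(cp)), decreasing = TRUE)
  r
}

# direct-sum potential energy oracle (plain R triple loop, no tricks)
oracle_energy <- function(loop, cfg) {
  N <- nrow(loop)
  E <- 0
  for (i in seq_len(N)) {
    j <- if (i == N) 1L else i + 1L
    r <- sqrt(sum((loop[i, ] - loop[j, ])^2))
    E <- E + 0.5 * cfg$kbond * (r - cfg$r0)^2
  }
  pair <- function(A, r2) {
    if (r2 >= cfg$vdw_cutoff^2) return(0)
    min(A / r2^6, cfg$ecap)
  }
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (j <= i) next
    dj <- min(j - i, N - (j - i))
    if (dj <= 1) next
    E <- E + pair(cfg$vdw_A, sum((loop[i, ] - loop[j, ])^2))
  }
  if (cfg$N_B > 0) {
    for (i in seq_len(N)) {
      rho2 <- loop[i, 2]^2 + loop[i, 3]^2
      for (j in -200:200) {  # generous slab of periodic thread beads
        dx <- loop[i, 1] - j * cfg$r0
        E <- E + pair(cfg$A_thread, dx^2 + rho2)
      }
    }
  }
  E
}

# winding number by explicit angle accumulation (independent of the
# compiled routine's bookkeeping)
oracle_winding <- function(loop) {
  ang <- atan2(loop[, 3], loop[, 2])
  d <- diff(c(ang, ang[1]))
  d <- (d + pi) %% (2 * pi) - pi
  sum(d) / (2 * pi)
}

# random rigid motion
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3))) * sample(c(-1, 1), 1)
}

make_loop <- function(vertices, edge_length = 1) {
  structure(list(vertices = vertices, edge_length = edge_length,
                 n_edges = nrow(vertices)),
            class = "loop_conformation")
}

make_lasso <- function(loop_vertices, tails, anchors = NULL) {
  if (is.null(anchors)) anchors <- rep(1L, length(tails))
  structure(list(loop = make_loop(loop_vertices), tails = tails,
                 anchor_indices = anchors),
            class = "lasso_conformation")
}
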