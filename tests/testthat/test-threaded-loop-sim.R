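# Metropolis Monte Carlo of the (optionally threaded) excluded-volume loop.

test_that("minimal loop sizes and thread bead counts follow the model", {
  expect_s3_class(sim_config(N = 3, w = 0), "sim_config")
  expect_error(sim_config(N = 5, w = 2), "too-small-loop")
  expect_identical(sim_config(N = 10, w = 1)$N_B, 12L)
  expect_identical(sim_config(N = 40, w = 1)$N_B, 25L)
  expect_equal(sim_config(N = 10, w = 1)$box, 0.38 * 12)
})

test_that("potential energy matches closed forms and the direct-sum oracle", {
  cfg <- sim_config(N = 3, w = 0)
  r0 <- cfg$r0
  tri <- rbind(c(0, 0, 0), c(r0, 0, 0), c(r0 / 2, r0 * sqrt(3) / 2, 0))
  expect_equal(potential_energy(tri, cfg), 0, tolerance = 1e-12)
  # one stretched pair in an open-ish 3-bead loop: bond terms only
  delta <- 0.01
  tri2 <- tri
  tri2[2, 1] <- r0 + delta
  e_hand <- 0.5 * cfg$kbond * delta^2 +
    0.5 * cfg$kbond * (sqrt(sum((tri2[2, ] - tri2[3, ])^2)) - r0)^2
  expect_equal(potential_energy(tri2, cfg), e_hand, tolerance = 1e-10)
  # random frames vs brute-force oracle, unthreaded and threaded
  set.seed(71)
  for (cfg2 in list(sim_config(N = 6, w = 0), sim_config(N = 8, w = 2))) {
    for (i in 1:50) {
      loop <- matrix(rnorm(cfg2$N * 3, sd = 0.4), ncol = 3)
      loop[, 1] <- loop[, 1] + cfg2$box / 2
      expect_equal(potential_energy(loop, cfg2),
                   oracle_energy(loop, cfg2), tolerance = 1e-10)
    }
  }
})

test_that("overlapping beads give a large but finite capped energy", {
  cfg <- sim_config(N = 4, w = 0)
  loop <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(1e-12, 1e-12, 0),
                c(0, 0.38, 0))
  e <- potential_energy(loop, cfg)
  expect_true(is.finite(e))
  expect_gte(e, cfg$ecap)  # the overlapping pair is capped at ecap
})

test_that("near-zero temperature runs never increase the energy", {
  cfg <- sim_config(N = 12, w = 0, T = 1e-7, sweeps = 60, stride = 1,
                    tune_sweeps = 0, seed = 4)
  traj <- run_simulation(cfg)
  expect_true(all(diff(traj$energies) <= 1e-9))
})

test_that("runs are deterministic given config and seed", {
  cfg <- sim_config(N = 10, w = 0, T = 100, sweeps = 50, stride = 5,
                    tune_sweeps = 20, seed = 99)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
})

test_that("3-bead bond lengths follow the Boltzmann weight from quadrature", {
  cfg <- sim_config(N = 3, w = 0, T = 10, sweeps = 6000, stride = 1,
                    tune_sweeps = 300, seed = 13)
  traj <- run_simulation(cfg)
  fr <- traj$frames
  nf <- dim(fr)[3]
  bonds <- sqrt(colSums((fr[1, , ] - fr[2, , ])^2))
  # quadrature over side lengths (r1, r2, r3): the configurational measure
  # of three points in R^3 reduced by rigid motions is r1 r2 r3 dr1 dr2 dr3
  kT <- cfg$kT
  r0 <- cfg$r0
  gr <- seq(r0 - 6 * sqrt(kT / cfg$kbond), r0 + 6 * sqrt(kT / cfg$kbond),
            length.out = 61)
  wgrid <- expand.grid(r1 = gr, r2 = gr, r3 = gr)
  en <- 0.5 * cfg$kbond * ((wgrid$r1 - r0)^2 + (wgrid$r2 - r0)^2 +
                             (wgrid$r3 - r0)^2)
  dens <- wgrid$r1 * wgrid$r2 * wgrid$r3 * exp(-en / kT)
  m_or <- sum(wgrid$r1 * dens) / sum(dens)
  v_or <- sum((wgrid$r1 - m_or)^2 * dens) / sum(dens)
  n_eff <- nf / 5  # conservative for residual autocorrelation
  expect_lt(abs(mean(bonds) - m_or), 3 * sqrt(v_or / n_eff))
  expect_lt(abs(sd(bonds) - sqrt(v_or)), 3 * sqrt(v_or / n_eff))
})

test_that("chord correlation is 1 at lag 0, 1 for frozen frames, 0 for noise", {
  N <- 10
  frozen <- array(rep(cbind(cos(2 * pi * (1:N) / N),
                            sin(2 * pi * (1:N) / N), 0), 5), c(N, 3, 5))
  cc <- chord_correlation(frozen, lags = 0:4)
  expect_equal(cc$C, rep(1, 5), tolerance = 1e-12)
  expect_equal(cc$C[1], 1)
  set.seed(15)
  nf <- 200
  rnd <- array(0, c(N, 3, nf))
  for (f in seq_len(nf)) {
    # fresh random chain each frame: chords are independent across frames
    rnd[, , f] <- apply(matrix(rnorm(N * 3), ncol = 3), 2, cumsum)
  }
  ccr <- chord_correlation(rnd, lags = c(0, 1, 3))
  se <- 1 / sqrt(N * (nf - 3))
  expect_lt(abs(ccr$C[2]), 3 * se * 2)
  expect_lt(abs(ccr$C[3]), 3 * se * 2)
  expect_error(chord_correlation(frozen[, , 1, drop = FALSE]),
               "at least 2")
})

test_that("winding checks match the angle-sum oracle and detect off-axis loops", {
  cfg <- sim_config(N = 12, w = 1)
  fr <- build_system(cfg)
  expect_true(check_threading(fr, cfg))
  off <- fr$loop
  off[, 2] <- off[, 2] + 10 * cfg$box
  expect_false(check_threading(off, cfg))
  set.seed(17)
  for (i in 1:10) {
    # random deformations that keep every bead off the axis
    loop <- fr$loop
    loop[, 2:3] <- loop[, 2:3] * runif(nrow(loop), 0.5, 2)
    loop[, 1] <- loop[, 1] + rnorm(nrow(loop), sd = 0.1)
    w_impl <- round(lassopoly:::cpp_winding_number(loop))
    expect_equal(w_impl, round(oracle_winding(loop)))
    expect_equal(abs(w_impl), 1)
  }
})

test_that("threading is conserved in every recorded frame for w > 0", {
  for (w in c(1L, 3L)) {
    cfg <- sim_config(N = 14, w = w, T = 100, sweeps = 400, stride = 2,
                      tune_sweeps = 100, seed = 20 + w)
    traj <- run_simulation(cfg)
    expect_true(all(traj$threaded == 1L))
  }
})

test_that("mean Rg grows with N and threading elevates the distension", {
  sweep_tab <- run_shape_sweep(c(12, 20, 32), w = 0, T = 100,
                               sweeps = 1400, stride = 2,
                               tune_sweeps = 150, master_seed = 5,
                               min_frames = 40)
  expect_true(all(diff(sweep_tab$Rg) > 3 *
                    sqrt(sweep_tab$Rg_se[-1]^2 + sweep_tab$Rg_se[-3]^2) *
                    -1))
  expect_true(all(diff(sweep_tab$Rg) > 0))
  # tightly threaded small loops rotate slowly about the thread, so the
  # chord correlation decays sluggishly: use an explicit generous burn-in
  thr <- run_shape_sweep(20, w = 2, T = 100, sweeps = 2000, stride = 2,
                         tune_sweeps = 150, master_seed = 5,
                         min_frames = 50, burn_in = 200)
  un <- sweep_tab[sweep_tab$N == 20, ]
  expect_gt(thr$D - un$D, -3 * sqrt(thr$D_se^2 + un$D_se^2))
  expect_gt(thr$D, un$D)
})
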