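# Protein bridge: PDB reading, loop/tail extraction, classification on
# synthetic fixtures with known ground truth, threading probabilities.

fixture <- function(...) {
  f <- tempfile(fileext = ".pdb")
  synthetic_lasso_pdb(f, ...)
}

# a surface fit with flat probability surface P(N, t) = p0 (amplitudes 0)
flat_surface_fit <- function(p0) {
  structure(list(params = c(Pinf = p0, ca_t = 0, alpha_t = 1, ca_N = 0,
                            alpha_N = 1, cb_t = 0, beta_t = 0.01, cb_N = 0,
                            beta_N = 0.01)),
            class = "surface_fit")
}

test_that("SSBOND records and chain geometry are read (40-residue fixture)", {
  f <- fixture(loop_size = 26, t1 = 4, t2 = 10, threading = "single")
  ch <- read_chain(f)
  expect_identical(nrow(ch$ca), 40L)
  expect_identical(nrow(ch$bridges), 1L)
  expect_equal(ch$bridges[1, ], c(5, 30))
  # CA-like spacing (chords across path corners shrink slightly)
  steps <- sqrt(rowSums(diff(ch$ca)^2))
  expect_true(all(steps > 0.2 & steps < 0.42))
})

test_that("bridges are detected geometrically from SG atoms", {
  f <- fixture(loop_size = 26, t1 = 4, t2 = 10, threading = "single",
               ssbond = FALSE, sg_atoms = TRUE)
  ch <- read_chain(f)
  expect_equal(ch$bridges[1, ], c(5, 30))
})

test_that("chains without cysteines have no bridges", {
  f <- tempfile(fileext = ".pdb")
  th <- seq(0, 4 * pi, length.out = 20)
  writeLines(c(vapply(seq_along(th), function(i)
    lassopoly:::pdb_atom_line(i, "CA", "ALA", "A", i,
                              c(3.8 * i, cos(th[i]), sin(th[i]))),
    ""), "END"), f)
  ch <- read_chain(f)
  expect_identical(nrow(ch$bridges), 0L)
  expect_error(extract_lassos(ch), "no bridges")
})

test_that("loop/tail extraction partitions the chain", {
  f <- fixture(loop_size = 26, t1 = 4, t2 = 10, threading = "single")
  ch <- read_chain(f)
  bl <- extract_lassos(ch)[[1]]
  expect_identical(bl$N, 26L)
  expect_identical(bl$t1, 4L)
  expect_identical(bl$t2, 10L)
  expect_identical(bl$N + bl$t1 + bl$t2, nrow(ch$ca))
  # bridge spanning the whole chain: no tails
  ch2 <- ch
  bl2 <- extract_lassos(ch, bridges = cbind(1, 40))[[1]]
  expect_identical(bl2$t1, 0L)
  expect_identical(bl2$t2, 0L)
  expect_identical(bl2$N, 40L)
  # two bridges give two records
  bls <- extract_lassos(ch, bridges = rbind(c(5, 30), c(6, 29)))
  expect_length(bls, 2L)
})

test_that("fixture classification matches the constructed ground truth", {
  cases <- list(single = "L1", double = "L2", none = "L0")
  for (nm in names(cases)) {
    f <- fixture(loop_size = 26, t1 = 4, t2 = 10, threading = nm)
    bl <- extract_lassos(read_chain(f))[[1]]
    expect_identical(classify_protein_lasso(bl)$label, cases[[nm]])
    expect_identical(attr(f, "truth"), cases[[nm]])
  }
  fb <- fixture(loop_size = 26, t1 = 6, t2 = 10, threading = "both")
  blb <- extract_lassos(read_chain(fb))[[1]]
  expect_identical(classify_protein_lasso(blb)$label, "LL_1,1")
})

test_that("packaged synthetic structures classify as labelled", {
  cases <- c(L0 = "synthetic_lasso_L0.pdb", L1 = "synthetic_lasso_L1.pdb")
  for (lab in names(cases)) {
    f <- system.file("extdata", cases[[lab]], package = "lassopoly")
    bl <- extract_lassos(read_chain(f))[[1]]
    expect_identical(classify_protein_lasso(bl)$label, lab)
  }
})

test_that("threading probabilities follow inclusion-exclusion", {
  fit <- flat_surface_fit(0.5)   # p_tail = 1 - 0.5 = 0.5 for any tail
  bl <- structure(list(N = 30L, t1 = 10L, t2 = 10L), class = "bridge_loop")
  est <- threading_probability(bl, fit)
  expect_equal(est$p_tail, c(0.5, 0.5))
  expect_equal(est$p_any, 0.75)
  bl0 <- structure(list(N = 30L, t1 = 0L, t2 = 0L), class = "bridge_loop")
  expect_equal(threading_probability(bl0, fit)$p_any, 0)
  # single tail at the asymptote: p = 1 - Pinf
  fit19 <- flat_surface_fit(0.19)
  bl1 <- structure(list(N = 1e6L, t1 = 1e6L, t2 = 0L),
                   class = "bridge_loop")
  expect_equal(threading_probability(bl1, fit19)$p_any, 1 - 0.19)
  # multi-piercing adjustment via the geometric model
  est3 <- threading_probability(bl1, fit19, n_pierce = 3)
  expect_equal(est3$p_adjusted, (1 - 0.19) * (1 - 0.19)^2)
  expect_error(threading_probability(bl1, list()), "configuration error")
})

test_that("chain-level aggregation and monotonicity in tail length", {
  fit <- flat_surface_fit(0.5)
  bl <- structure(list(N = 30L, t1 = 10L, t2 = 0L), class = "bridge_loop")
  e <- threading_probability(bl, fit)
  expect_equal(chain_threading_probability(list(e, e)), 0.75)
  # P(>=1) non-decreasing in tail length under a fitted decaying surface
  dec <- structure(list(params = c(Pinf = 0.19, ca_t = 0.3, alpha_t = 0.1,
                                   ca_N = 0.2, alpha_N = 0.05, cb_t = 0.2,
                                   beta_t = 0.01, cb_N = 0.1,
                                   beta_N = 0.005)), class = "surface_fit")
  ps <- vapply(c(1, 5, 20, 80, 300), function(tl) {
    blt <- structure(list(N = 50L, t1 = tl, t2 = 0L),
                     class = "bridge_loop")
    threading_probability(blt, dec)$p_any
  }, 0)
  expect_true(all(diff(ps) >= 0))
})

test_that("candidate selection and expected-vs-observed bookkeeping", {
  est <- data.frame(label = c("L1", "L1", "L0"),
                    p_model = c(0.1, 0.5, 0.05))
  sel <- select_candidates(est)
  expect_identical(nrow(sel), 1L)
  expect_equal(sel$p_model, 0.1)
  chains <- data.frame(length = rep(120, 10), p_any = rep(0.3, 10),
                       label = c(rep("L1", 3), rep("L0", 7)))
  evo <- expected_vs_observed(chains, bin_width = 50)
  expect_identical(nrow(evo), 1L)
  expect_equal(evo$expected, 3)
  expect_identical(evo$observed, 3L)
  all_trivial <- data.frame(length = c(40, 300), p_any = 0.1,
                            label = "L0")
  evo2 <- expected_vs_observed(all_trivial, bin_width = 50)
  expect_true(all(evo2$observed == 0))
  expect_identical(nrow(evo2), 2L)  # empty bins omitted
})
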