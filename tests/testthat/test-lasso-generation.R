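# Uniform equilateral polygon sampling, random-walk tails, ensembles.

closure_edges <- function(v) {
  n <- nrow(v)
  sqrt(rowSums((v[c(2:n, 1L), ] - v)^2))
}

test_that("the unit triangle is rigid", {
  loop <- sample_equilateral_polygon(3)
  v <- loop$vertices
  d <- as.matrix(dist(v))
  expect_equal(d[upper.tri(d)], rep(1, 3), tolerance = 1e-12)
})

test_that("sampled polygons are closed and equilateral to 1e-9", {
  set.seed(101)
  for (k in c(4, 5, 10, 50, 137)) {
    for (rep in 1:3) {
      v <- sample_equilateral_polygon(k)$vertices
      expect_lt(max(abs(closure_edges(v) - 1)), 1e-9)
      expect_true(all(is.finite(v)))
    }
  }
})

test_that("invalid arguments are rejected", {
  expect_error(sample_equilateral_polygon(2), ">= 3")
  expect_error(sample_random_walk_tail(-1), ">= 0")
  expect_error(build_lasso(sample_equilateral_polygon(10), c(5, 5, 5)),
               "at most 2 tails")
})

test_that("diagonal-validity acceptance rate matches the brute-force oracle", {
  k <- 6
  set.seed(77)
  n_impl <- 4000
  att <- vapply(seq_len(n_impl), function(i)
    sample_equilateral_polygon(k)$attempts, 0)
  p_impl <- n_impl / sum(att)
  n_or <- 20000
  p_or <- oracle_diagonal_acceptance(k, n_or)
  se <- sqrt(p_or * (1 - p_or) / n_or + p_impl * (1 - p_impl) / sum(att))
  expect_lt(abs(p_impl - p_or), 3 * se)
})

test_that("random-walk tails have unit steps, correct origin and E|R|^2 = t", {
  expect_equal(sample_random_walk_tail(0, c(1, 2, 3)),
               matrix(c(1, 2, 3), 1))
  set.seed(5)
  tl <- sample_random_walk_tail(100, c(1, 0, 0))
  expect_equal(tl[1, ], c(1, 0, 0))
  expect_lt(max(abs(sqrt(rowSums(diff(tl)^2)) - 1)), 1e-12)
  t_len <- 64
  n <- 20000
  set.seed(6)
  r2 <- replicate(n, {
    w <- sample_random_walk_tail(t_len)
    sum(w[t_len + 1, ]^2)
  })
  se <- sd(r2) / sqrt(n)
  expect_lt(abs(mean(r2) - t_len), 3 * se)
})

test_that("build_lasso anchors tails at the origin-translated bridge vertex", {
  set.seed(9)
  l0 <- build_lasso(sample_equilateral_polygon(10))
  expect_identical(length(l0$tails), 0L)
  l1 <- build_lasso(sample_equilateral_polygon(10), 20)
  expect_equal(l1$loop$vertices[1, ], c(0, 0, 0))
  expect_equal(nrow(l1$tails[[1]]), 21L)
  expect_equal(l1$tails[[1]][1, ], c(0, 0, 0))
  l2 <- build_lasso(sample_equilateral_polygon(10), c(5, 5))
  expect_equal(vapply(l2$tails, function(tl) tl[1, ], numeric(3)),
               matrix(0, 3, 2))
  expect_false(isTRUE(all.equal(l2$tails[[1]], l2$tails[[2]])))
})

test_that("ensembles are deterministic given the master seed", {
  spec <- ensemble_spec(10, 10, 5, master_seed = 42)
  e1 <- generate_ensemble(spec)
  e2 <- generate_ensemble(spec)
  expect_identical(e1, e2)
  spec2 <- ensemble_spec(c(10, 12), 10, 4, master_seed = 7)
  e3 <- generate_ensemble(spec2)
  expect_length(e3, 8L)
  cells <- t(vapply(e3, function(x) c(x$cell$N, x$cell$t), numeric(2)))
  expect_equal(as.vector(table(cells[, 1])), c(4L, 4L))
})

test_that("mean squared loop Rg agrees with an independent fold-MCMC sampler", {
  N <- 20
  set.seed(11)
  n <- 3000
  rg2_impl <- replicate(n, {
    v <- sample_equilateral_polygon(N)$vertices
    mean(rowSums(sweep(v, 2, colMeans(v))^2))
  })
  rg2_or <- oracle_fold_mcmc_rg2(N, n_moves = 40000, sample_every = 10)
  # conservative SE for the (autocorrelated) MCMC stream
  se <- sqrt(sd(rg2_impl)^2 / n + 10 * sd(rg2_or)^2 / length(rg2_or))
  expect_lt(abs(mean(rg2_impl) - mean(rg2_or)), 3 * se)
})

test_that("rotation invariance: rotated loops give the same Rg distribution", {
  set.seed(21)
  n <- 400
  rg_plain <- replicate(n, radius_of_gyration(
    sample_equilateral_polygon(12)$vertices))
  rg_rot <- replicate(n, {
    v <- sample_equilateral_polygon(12)$vertices %*% random_rotation()
    radius_of_gyration(v)
  })
  expect_gt(suppressWarnings(ks.test(rg_plain, rg_rot)$p.value), 0.01)
})

test_that("child seeds are valid and sensitive to every index", {
  s <- child_seed(1, 10, 20, 3)
  expect_true(s == as.integer(s) && s >= 0 && s < 2^31)
  expect_false(child_seed(1, 10, 20, 3) == child_seed(1, 10, 20, 4))
  expect_false(child_seed(1, 10, 20, 3) == child_seed(1, 11, 20, 3))
  expect_false(child_seed(1, 10, 20, 3) == child_seed(2, 10, 20, 3))
})
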