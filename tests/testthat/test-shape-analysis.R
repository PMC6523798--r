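# Shape descriptors and scaling-law fits.

regular_ngon <- function(N, R = 1) {
  th <- 2 * pi * (seq_len(N) - 1) / N
  cbind(R * cos(th), R * sin(th), 0)
}

test_that("radius of gyration: anchors and brute-force oracle", {
  expect_equal(radius_of_gyration(regular_ngon(17, R = 2.5)), 2.5,
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 0, 0))), 1.5)
  expect_error(radius_of_gyration(matrix(0, 1, 3)), "at least 2")
  set.seed(81)
  for (i in 1:100) {
    x <- matrix(rnorm(3 * sample(4:40, 1)), ncol = 3)
    expect_equal(radius_of_gyration(x), oracle_rg_bruteforce(x),
                 tolerance = 1e-12)
  }
})

test_that("distension anchors", {
  r0 <- 0.38
  for (N in c(5, 20, 100)) {
    R <- r0 / (2 * sin(pi / N))
    expect_equal(distension(regular_ngon(N, R), r0 = r0), 1,
                 tolerance = 1e-12)
    expect_equal(distension(1.1 * regular_ngon(N, R), r0 = r0), 1.1,
                 tolerance = 1e-12)
  }
  collapsed <- matrix(rep(c(1, 2, 3), each = 10), ncol = 3)
  expect_equal(distension(collapsed, r0 = r0), 0)
  expect_error(distension(matrix(0, 2, 3), N = 2), "at least 3")
})

test_that("gyration-tensor semi-axes: isotropy, rank deficiency, cubic oracle", {
  set.seed(82)
  z <- matrix(rnorm(3 * 20000), ncol = 3)
  sphere <- z / sqrt(rowSums(z^2))
  ax <- ellipsoid_semi_axes(sphere)
  expect_lt(ax["a"] / ax["c"] - 1, 0.05)
  planar <- cbind(rnorm(50), rnorm(50), 0)
  expect_lt(ellipsoid_semi_axes(planar)["c"], 1e-12)
  for (i in 1:100) {
    x <- matrix(rnorm(3 * sample(5:30, 1)), ncol = 3)
    ev_impl <- ellipsoid_semi_axes(x)^2
    ev_or <- oracle_gyration_eigenvalues(x)
    expect_equal(unname(ev_impl), ev_or, tolerance = 1e-8)
  }
  # Rg^2 = a^2 + b^2 + c^2
  x <- matrix(rnorm(60), ncol = 3)
  expect_equal(sum(ellipsoid_semi_axes(x)^2), radius_of_gyration(x)^2,
               tolerance = 1e-12)
})

test_that("asphericity anchors: sphere, disk, stick", {
  expect_equal(asphericity(1, 1, 1), 0)
  expect_equal(asphericity(1, 1, 0), 0.25)
  expect_equal(asphericity(1, 0, 0), 1)
  expect_error(asphericity(0, 0, 0), "all-zero")
})

test_that("prolateness anchors, range, and undefined sphere", {
  expect_equal(prolateness(2, 1, 1), 1)
  expect_equal(prolateness(2, 2, 1), -1)
  expect_error(prolateness(1, 1, 1), "undefined-prolateness")
  set.seed(83)
  for (i in 1:200) {
    ax <- sort(runif(3), decreasing = TRUE)
    if (abs(ax[1] - ax[3]) < 1e-9) next
    p <- prolateness(ax)
    expect_gte(p, -1 - 1e-12)
    expect_lte(p, 1 + 1e-12)
  }
})

test_that("descriptors transform correctly under rigid motion and scaling", {
  set.seed(84)
  x <- matrix(rnorm(45), ncol = 3)
  Q <- random_rotation()
  y <- sweep(x %*% Q, 2, c(3, -1, 2), "+")
  expect_equal(radius_of_gyration(y), radius_of_gyration(x),
               tolerance = 1e-12)
  expect_equal(ellipsoid_semi_axes(y), ellipsoid_semi_axes(x),
               tolerance = 1e-9)
  s <- 2.7
  expect_equal(radius_of_gyration(s * x), s * radius_of_gyration(x),
               tolerance = 1e-12)
  expect_equal(unname(ellipsoid_semi_axes(s * x)),
               unname(s * ellipsoid_semi_axes(x)), tolerance = 1e-9)
  expect_equal(asphericity(ellipsoid_semi_axes(s * x)),
               asphericity(ellipsoid_semi_axes(x)), tolerance = 1e-9)
  expect_equal(prolateness(ellipsoid_semi_axes(s * x)),
               prolateness(ellipsoid_semi_axes(x)), tolerance = 1e-8)
  expect_equal(distension(s * x), s * distension(x), tolerance = 1e-12)
})

test_that("noiseless scaling laws are recovered", {
  N <- c(30, 50, 80, 120, 200, 300)
  rg <- -0.1 + 0.15 * N^0.59
  fit_free <- fit_rg_scaling(data.frame(N = N, Rg = rg, Rg_se = 1e-3),
                             mode = "free")
  expect_equal(unname(fit_free$params), c(-0.1, 0.15, 0.59),
               tolerance = 1e-6)
  fit_fixed <- fit_rg_scaling(data.frame(N = N, Rg = rg, Rg_se = 1e-3),
                              mode = "fixed")
  expect_equal(unname(fit_fixed$params[c("c_r", "a_r")]), c(-0.1, 0.15),
               tolerance = 1e-8)
  aa <- 0.0708 + 0.12 * N^-0.8
  fit_a <- fit_asphericity_scaling(data.frame(N = N, A = aa, A_se = 1e-4))
  expect_equal(unname(fit_a$params), c(0.0708, 0.12, -0.8),
               tolerance = 1e-4)
  pp <- 0.3 - 1.4 * N^-0.47
  fit_p <- fit_prolateness_scaling(data.frame(N = N, P = pp, P_se = 1e-3))
  expect_equal(unname(fit_p$params), c(0.3, -1.4), tolerance = 1e-8)
})

test_that("fits refuse underdetermined input", {
  expect_error(fit_rg_scaling(data.frame(N = c(30, 50), Rg = c(1, 2),
                                         Rg_se = c(0.1, 0.1))), ">= 4")
  expect_error(fit_asphericity_scaling(
    data.frame(N = c(10, 20, 25), A = 1:3, A_se = 1)), ">= 4")
})

test_that("shape_record bundles consistent descriptors", {
  set.seed(85)
  x <- matrix(rnorm(60, sd = 0.5), ncol = 3)
  rec <- shape_record(x, r0 = 0.38)
  expect_equal(rec$Rg, radius_of_gyration(x))
  expect_equal(rec$A, asphericity(rec$semi_axes))
  expect_equal(rec$P, prolateness(rec$semi_axes))
  expect_true(rec$semi_axes["a"] >= rec$semi_axes["b"] &&
                rec$semi_axes["b"] >= rec$semi_axes["c"])
})
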