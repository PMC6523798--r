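# Minimal-surface spanning and signed piercing counts.

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)

test_that("a planar convex loop spans its flat polygon area", {
  th <- 2 * pi * (0:11) / 12
  poly <- cbind(cos(th), sin(th), 0)
  s <- span_minimal_surface(poly)
  area_true <- 12 * 0.5 * sin(2 * pi / 12)
  expect_lt(abs(s$area - area_true) / area_true, 1e-3)
})

test_that("a regular 64-gon converges to the disk area within 2%", {
  R <- 2
  th <- 2 * pi * (0:63) / 64
  s <- span_minimal_surface(cbind(R * cos(th), R * sin(th), 0))
  expect_lt(abs(s$area - pi * R^2) / (pi * R^2), 0.02)
})

test_that("relaxation never increases the area above the initial fan", {
  set.seed(31)
  for (i in 1:8) {
    v <- sample_equilateral_polygon(30)$vertices
    s <- span_minimal_surface(v)
    expect_lte(s$area, s$area_initial + 1e-12)
  }
})

test_that("a collinear loop raises a degenerate-surface error", {
  bad <- cbind(seq(0, 1, length.out = 6), 0, 0)
  expect_error(span_minimal_surface(bad), "degenerate-surface")
})

test_that("hand-constructed tails give the expected crossings", {
  s <- span_minimal_surface(unit_square, target_edge = 0.25)
  # dips below at the anchor corner, rises through the centre: one +1
  up <- rbind(c(0, 0, 0), c(0.5, 0.5, -1), c(0.5, 0.5, 2))
  pr <- count_piercings(s, up, 1)
  expect_identical(pr$n_total, 1L)
  expect_identical(pr$crossings$sign, 1L)
  # stays above the plane after leaving the anchor: no crossings
  clear <- rbind(c(0, 0, 0), c(-0.5, -0.5, 1), c(-2, -2, 2))
  expect_identical(count_piercings(s, clear, 1)$n_total, 0L)
  # there and back through two interior points: 2 crossings, signed sum 0
  tb <- rbind(c(0, 0, 0), c(0.3, 0.3, 1), c(0.35, 0.35, -1),
              c(0.6, 0.6, 1))
  pr2 <- count_piercings(s, tb, 1)
  expect_identical(pr2$n_total, 2L)
  expect_identical(pr2$signed_sum, 0L)
  expect_identical(sort(pr2$crossings$sign), c(-1L, 1L))
  # crossings are ordered along the tail
  expect_identical(pr2$crossings$segment, sort(pr2$crossings$segment))
})

test_that("non-finite input is rejected", {
  s <- span_minimal_surface(unit_square)
  expect_error(count_piercings(s, rbind(c(0, 0, 0), c(NA, 1, 1))),
               "non-finite")
  expect_error(span_minimal_surface(rbind(c(0, 0, 0), c(Inf, 0, 0),
                                          c(0, 1, 0))), "non-finite")
})

test_that("classification labels follow the piercing counts", {
  la0 <- make_lasso(unit_square, list())
  expect_identical(classify_lasso(la0)$label, "L0")
  up <- rbind(c(0, 0, 0), c(0.5, 0.5, -1), c(0.5, 0.5, 2))
  la1 <- make_lasso(unit_square, list(up))
  cl1 <- classify_lasso(la1)
  expect_identical(cl1$label, "L1")
  expect_identical(cl1$n_piercings_total, 1L)
  tb <- rbind(c(0, 0, 0), c(0.3, 0.3, 1), c(0.35, 0.35, -1),
              c(0.6, 0.6, 1))
  expect_identical(classify_lasso(make_lasso(unit_square, list(tb)))$label,
                   "L2")
  ll <- classify_lasso(make_lasso(unit_square, list(up, tb)))
  expect_identical(ll$label, "LL_1,2")
  one_sided <- classify_lasso(make_lasso(unit_square, list(up, clear = rbind(
    c(0, 0, 0), c(-1, -1, 1)))))
  expect_identical(one_sided$label, "L1")
})

test_that("classification is invariant under rigid motion and scaling", {
  set.seed(41)
  for (i in 1:5) {
    la <- build_lasso(sample_equilateral_polygon(16), 16)
    lab <- classify_lasso(la)$label
    Q <- random_rotation()
    shift <- rnorm(3, sd = 5)
    sc <- runif(1, 0.2, 5)
    v2 <- sweep(sc * la$loop$vertices %*% Q, 2, shift, "+")
    t2 <- sweep(sc * la$tails[[1]] %*% Q, 2, shift, "+")
    la2 <- make_lasso(v2, list(t2))
    expect_identical(classify_lasso(la2)$label, lab)
  }
})

test_that("reversing the tail flips signs but keeps count and class", {
  s <- span_minimal_surface(unit_square, target_edge = 0.25)
  tb <- rbind(c(0, 0, 0), c(0.3, 0.3, 1), c(0.35, 0.35, -1),
              c(0.6, 0.6, 1))
  fwd <- count_piercings(s, tb, 1)
  rev_ <- count_piercings(s, tb[rev(seq_len(nrow(tb))), ], 1)
  expect_identical(fwd$n_total, rev_$n_total)
  expect_identical(sort(fwd$crossings$sign), sort(-rev_$crossings$sign))
})

test_that("signed-sum parity is invariant under mesh refinement", {
  set.seed(51)
  for (i in 1:6) {
    la <- build_lasso(sample_equilateral_polygon(14), 10)
    # push the tail endpoint far from the loop so the crossing parity is
    # a topological invariant of the (loop, tail) pair
    far <- la$tails[[1]][11, ]
    far <- far / max(sqrt(sum(far^2)), 1e-9) * 50
    tail_far <- rbind(la$tails[[1]], far)
    s_coarse <- span_minimal_surface(la$loop, target_edge = 1)
    s_fine <- span_minimal_surface(la$loop, target_edge = 0.5, tol = 1e-5)
    p1 <- count_piercings(s_coarse, tail_far, 1)
    p2 <- count_piercings(s_fine, tail_far, 1)
    expect_identical(p1$signed_sum %% 2, p2$signed_sum %% 2)
    expect_identical(p1$signed_sum, p2$signed_sum)
  }
})

test_that("piercing record invariants hold on random lassos", {
  set.seed(61)
  for (i in 1:10) {
    la <- build_lasso(sample_equilateral_polygon(20), 20)
    cl <- classify_lasso(la)
    pr <- cl$records[[1]]
    expect_lte(abs(pr$signed_sum), pr$n_total)
    expect_identical(pr$n_total %% 2, abs(pr$signed_sum) %% 2)
    expect_identical(cl$label == "L0", pr$n_total == 0L)
  }
})
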