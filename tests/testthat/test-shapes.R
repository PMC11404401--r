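test_that("isoperimetric quotient matches its closed-form anchors", {
  r <- 2.7
  expect_equal(iso_quotient(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  expect_equal(round(iso_quotient(polypotts:::polygon_geometry(regular_polygon(5))$area,
                                  polypotts:::polygon_geometry(regular_polygon(5))$perimeter), 3),
               0.930)
  expect_equal(iso_quotient(1, 4), sqrt(4 * pi) / 4, tolerance = 1e-12)
  expect_equal(round(iso_quotient(1, 4), 5), 0.88623)
  expect_error(iso_quotient(-1, 4), "positive")
})

test_that("q_reg reproduces the printed regular-polygon values and limits", {
  expect_equal(round(q_reg(5), 3), 0.930)
  expect_equal(round(q_reg(6), 3), 0.952)
  expect_lt(1 - q_reg(1e6), 1e-10)
  # strictly increasing on [3, 64]
  n <- seq(3, 64, by = 0.25)
  expect_true(all(diff(q_reg(n)) > 0))
  # agrees with the explicit polygon construction at integers
  for (k in c(3, 4, 7, 11)) {
    g <- polypotts:::polygon_geometry(regular_polygon(k))
    expect_equal(q_reg(k), iso_quotient(g$area, g$perimeter), tolerance = 1e-12)
  }
  expect_error(q_reg(2.5), "at least 3")
})

test_that("n_star inverts q_reg to high precision", {
  expect_equal(round(n_star(0.930), 2), 5)
  expect_lt(abs(n_star(q_reg(7.3)) - 7.3), 1e-9)
  n <- c(3.2, 4.7, 5.5, 6.01, 9.9, 20)
  expect_equal(n_star(q_reg(n)), n, tolerance = 1e-9)

  # oracle: brute-force grid search for q = 0.99
  grid <- seq(3, 60, by = 1e-3)
  n0 <- grid[which.min(abs(q_reg(grid) - 0.99))]
  fine <- seq(n0 - 2e-3, n0 + 2e-3, by = 1e-6)
  n_oracle <- fine[which.min(abs(q_reg(fine) - 0.99))]
  expect_equal(n_star(0.99), n_oracle, tolerance = 1e-5)

  expect_warning(low <- n_star(0.5), "clamped")
  expect_equal(low, 3)
  expect_error(n_star(1), "below 1")
})

test_that("circularity matches closed forms and the Monte-Carlo moment oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(circularity(sq), 3 / pi, tolerance = 1e-12)
  expect_equal(polypotts::polygon_moments(sq)$trace, 1 / 6, tolerance = 1e-12)

  disk <- regular_polygon(4096, r = 1.3)
  expect_equal(circularity(disk), 1, tolerance = 1e-5)

  set.seed(21)
  irregular <- cbind(c(0, 2, 2.5, 1.4, 0.2), c(0, -0.3, 1.2, 2.1, 1.0))
  mc <- mc_circularity(irregular, n = 2e6)
  expect_lt(abs(circularity(irregular) - mc$C), 3 * mc$sigma)

  expect_error(circularity(cbind(c(0, 1), c(0, 0))), "degenerate")
  expect_error(circularity(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("shape measures are invariant under scaling, rotation and translation", {
  set.seed(22)
  poly <- regular_polygon(7, r = 2, phase = 0.4)
  g0 <- polypotts:::polygon_geometry(poly)
  q0 <- iso_quotient(g0$area, g0$perimeter)
  c0 <- circularity(poly)
  for (s in c(0.01, 3, 1e4)) {
    gs <- polypotts:::polygon_geometry(poly * s)
    expect_equal(iso_quotient(gs$area, gs$perimeter), q0, tolerance = 1e-12)
    expect_equal(circularity(poly * s), c0, tolerance = 1e-12)
  }
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(poly %*% R, 2, c(17, -4), "+")
  expect_equal(circularity(moved), c0, tolerance = 1e-10)
})

test_that("C_reg has the pentagon/square anchors and is invertible", {
  expect_equal(c_reg(4), 3 / pi, tolerance = 1e-12)
  for (k in c(3, 5, 6, 9)) {
    expect_equal(c_reg(k), circularity(regular_polygon(k)), tolerance = 1e-10)
  }
  n <- seq(3, 64, by = 0.25)
  expect_true(all(diff(c_reg(n)) > 0))
  expect_lt(1 - c_reg(1e6), 1e-10)
  expect_equal(c_pentagon(), c_reg(5))

  expect_equal(n_circ(c_reg(5)), 5, tolerance = 1e-9)
  nn <- c(3.5, 5.2, 8.8)
  expect_equal(n_circ(c_reg(nn)), nn, tolerance = 1e-9)
  expect_error(n_circ(1.2), "below 1")
  expect_warning(n3 <- n_circ(0.5), "clamped")
  expect_equal(n3, 3)
})

test_that("voronoi shapes reproduce regular references and conserve area", {
  d <- sqrt(2 * 40 / sqrt(3)); v <- d * sqrt(3) / 2
  tp <- polypotts:::triangular_centers(8, 8, d, v)
  box <- c(8 * d, 8 * v)
  sh <- voronoi_shapes(tp, box)
  expect_equal(sh$q_v, rep(q_reg(6), 64), tolerance = 1e-3)
  expect_equal(sh$n_star, rep(6, 64), tolerance = 1e-3)
  expect_equal(sum(sh$A), prod(box), tolerance = 1e-8)

  set.seed(23)
  pts <- cbind(stats::runif(80, 0, 30), stats::runif(80, 0, 30))
  sh2 <- voronoi_shapes(pts, c(30, 30))
  expect_equal(sum(sh2$A), 900, tolerance = 1e-8 * 900)
  # convexity bound: q_V <= q_reg(m) for an m-vertex convex cell
  polys <- attr(sh2, "polygons")
  m <- vapply(polys, nrow, numeric(1))
  expect_true(all(sh2$q_v <= q_reg(m) + 1e-9))
  expect_true(all(sh2$C_v <= 1 & sh2$C_v > 0))

  expect_error(voronoi_shapes(cbind(c(0.25, 0.75), c(0.5, 0.5)), c(1, 1)),
               "at least 4")
})

test_that("pseudo-polygon fractions follow the upper-inclusive binning rule", {
  tab <- pseudo_fractions(c(4.6, 5.5, 5.6))
  expect_equal(tab$fraction[tab$n == 5], 2 / 3)
  expect_equal(tab$fraction[tab$n == 6], 1 / 3)

  tab2 <- pseudo_fractions(rep(6, 10))
  expect_equal(tab2$fraction[tab2$n == 6], 1)

  set.seed(24)
  vals <- stats::runif(500, 3, 9.4)
  expect_equal(sum(pseudo_fractions(vals)$fraction), 1)
  # boundary: exactly n + 0.5 belongs to class n
  expect_equal(pseudo_fractions(c(5.5))$fraction[pseudo_fractions(c(5.5))$n == 5], 1)
  expect_error(pseudo_fractions(numeric(0)), "empty")
})

test_that("distribution summary finds planted modes and minima", {
  set.seed(25)
  uni <- stats::rnorm(50000, 0.9, 0.01)
  s1 <- distribution_summary(uni)
  expect_false(s1$bimodal)
  expect_equal(s1$peaks[1], 0.9, tolerance = 0.002 / 0.9)

  mix <- c(stats::rnorm(30000, 5, 0.15), stats::rnorm(30000, 6, 0.15))
  s2 <- distribution_summary(mix)
  expect_true(s2$bimodal)
  expect_equal(sort(s2$peaks), c(5, 6), tolerance = 0.05)
  expect_equal(s2$minimum, 5.5, tolerance = 0.1 / 5.5)

  s3 <- distribution_summary(rep(2.5, 200))
  expect_false(s3$bimodal)
  expect_equal(s3$peaks, 2.5)

  expect_error(distribution_summary(stats::rnorm(50)), "at least 100")
})
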