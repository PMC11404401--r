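test_that("square builder gives unit sites with a full Moore adjacency", {
  lat <- build_square_lattice(4, 4, 1)
  expect_equal(lat$n_sites, 16)
  expect_true(all(lengths(lat$neighbors) == 8))
  expect_equal(sum(lat$area), 16)
  expect_equal(lat$weight_mode, "uniform")
  expect_true(all(unlist(lat$weights) == 1))
  # 4 edge contacts of length = spacing, 4 corner contacts of length 0
  for (i in c(1, 6, 16))
    expect_equal(sort(lat$edge_lengths[[i]]), c(0, 0, 0, 0, 1, 1, 1, 1))

  lat2 <- build_square_lattice(3, 3, 2)
  expect_true(all(abs(lat2$area - 4) < 1e-12))
  expect_equal(lat2$mean_edge_length, 2)

  expect_error(build_square_lattice(2, 4, 1), "at least 3")
  expect_error(build_square_lattice(4, 4, 0), "spacing")
})

test_that("hexagonal builder gives six equal-weight neighbors and conserves area", {
  lat <- build_hexagonal_lattice(4, 4, 1)
  expect_true(all(lengths(lat$neighbors) == 6))
  expect_equal(sum(lat$area), 16, tolerance = 1e-10)

  ew <- build_hexagonal_lattice(4, 4, 1, weight_mode = "edge-weighted")
  expect_true(all(abs(unlist(ew$weights) - 1) < 1e-12))

  big <- build_hexagonal_lattice(6, 6, 39.80)
  expect_equal(sum(big$area), 36 * 39.80, tolerance = 1e-8 * 36 * 39.8)

  expect_error(build_hexagonal_lattice(4, 5, 1), "even")
})

test_that("periodic Voronoi lattices satisfy tessellation invariants", {
  set.seed(10)
  for (rep in 1:3) {
    n <- sample(20:60, 1)
    L <- c(stats::runif(1, 5, 12), stats::runif(1, 5, 12))
    pts <- cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]))
    lat <- build_voronoi_lattice(pts, L)    # validate_lattice runs inside
    expect_lt(abs(sum(lat$area) - prod(L)), 1e-8 * prod(L))
    expect_equal(lat$weight_mode, "edge-weighted")
    # convexity bound on the shape of every site polygon
    for (i in seq_len(n)) {
      g <- polypotts:::polygon_geometry(lat$vertices[[i]])
      q <- iso_quotient(g$area, g$perimeter)
      expect_lte(q, q_reg(nrow(lat$vertices[[i]])) + 1e-9)
    }
  }
})

test_that("Voronoi cells equal the brute-force half-plane oracle", {
  set.seed(11)
  for (rep in 1:4) {
    n <- sample(5:12, 1)
    L <- c(stats::runif(1, 2, 5), stats::runif(1, 2, 5))
    pts <- cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]))
    # reject point sets whose cells would wrap (sparse corners)
    lat <- tryCatch(build_voronoi_lattice(pts, L), error = function(e) NULL)
    if (is.null(lat)) next
    for (i in seq_len(n))
      expect_same_vertex_set(lat$vertices[[i]], oracle_voronoi_cell(pts, L, i))
  }
})

test_that("Voronoi of regular generator grids recovers the regular adjacencies", {
  # square grid: 4 edge-sharing neighbors plus 4 vertex-only contacts
  g <- as.matrix(expand.grid(x = (0:5) + 0.5, y = (0:5) + 0.5))
  sq <- build_voronoi_lattice(g, c(6, 6))
  expect_true(all(lengths(sq$neighbors) == 8))
  npos <- vapply(sq$edge_lengths, function(l) sum(l > 0), numeric(1))
  nzero <- vapply(sq$edge_lengths, function(l) sum(l == 0), numeric(1))
  expect_true(all(npos == 4))
  expect_true(all(nzero == 4))
  # zero-length contacts carry zero weight
  w0 <- mapply(function(w, l) w[l == 0], sq$weights, sq$edge_lengths)
  expect_true(all(unlist(w0) == 0))

  # triangular grid: regular hexagonal cells, 6 equal-weight neighbors
  d <- 1; v <- d * sqrt(3) / 2
  tp <- polypotts:::triangular_centers(6, 6, d, v)
  tri <- build_voronoi_lattice(tp, c(6 * d, 6 * v))
  expect_true(all(lengths(tri$neighbors) == 6))
  expect_true(all(abs(unlist(tri$weights) - 1) < 1e-9))
})

test_that("degenerate generator configurations are rejected", {
  # strip cells: collinear generators, every cell touches its own image
  expect_error(build_voronoi_lattice(cbind(c(0.125, 0.375, 0.625, 0.875),
                                           rep(0.5, 4)),
                                     c(1, 1)),
               "periodic image")
  expect_error(build_voronoi_lattice(cbind(c(0.25, 0.75), c(0.5, 0.5)), c(1, 1)),
               "at least 4")
  set.seed(3)
  pts <- cbind(stats::runif(8), stats::runif(8))
  pts[5, ] <- pts[2, ]   # exact duplicate
  expect_error(build_voronoi_lattice(pts, c(1, 1)), "duplicate")
})

test_that("lattice JSON round-trip is lossless and validated", {
  f <- withr::local_tempfile(fileext = ".json")
  lat <- build_square_lattice(4, 4, 1)
  save_lattice(lat, f)
  back <- load_lattice(f)
  expect_identical(back$neighbors, lat$neighbors)
  expect_equal(back$area, lat$area, tolerance = 1e-12)
  expect_equal(back$weight_mode, lat$weight_mode)

  set.seed(12)
  pts <- cbind(stats::runif(100, 0, 10), stats::runif(100, 0, 10))
  vl <- build_voronoi_lattice(pts, c(10, 10))
  f2 <- withr::local_tempfile(fileext = ".json")
  save_lattice(vl, f2)
  back2 <- load_lattice(f2)
  expect_equal(unlist(back2$weights), unlist(vl$weights), tolerance = 1e-12)
  expect_equal(back2$mean_edge_length, vl$mean_edge_length, tolerance = 1e-12)
  expect_lt(max(abs(unlist(back2$vertices) - unlist(vl$vertices))), 1e-12)

  # corrupting the adjacency must be caught on load
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$sites$neighbors[[1]] <- obj$sites$neighbors[[1]][-1]
  obj$sites$edge_lengths[[1]] <- obj$sites$edge_lengths[[1]][-1]
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f3, digits = NA, auto_unbox = TRUE)
  expect_error(load_lattice(f3), "symmetric")

  obj2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj2$box <- NULL
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f4, digits = NA, auto_unbox = TRUE)
  expect_error(load_lattice(f4), "missing field 'box'")
})

test_that("validate_lattice rejects broken invariants", {
  lat <- build_square_lattice(4, 4, 1)
  bad <- lat
  bad$area[1] <- bad$area[1] * 2
  expect_error(validate_lattice(bad), "sum to the box area")
  bad2 <- lat
  bad2$neighbors[[1]][1] <- 1L
  expect_error(validate_lattice(bad2), "own neighbor")
})
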