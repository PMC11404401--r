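# Independent oracles and shared fixtures for the test suite.

# ---- brute-force periodic Voronoi oracle ------------------------------------
# The cell of generator i is the intersection of the half-planes towards all
# 9 periodic images of all other generators (no shortcuts, no adjacency
# logic); implemented with a plain Sutherland-Hodgman clip.

oracle_clip <- function(poly, qx, qy, half) {
  m <- nrow(poly)
  s <- poly[, 1] * qx + poly[, 2] * qy - half
  eps <- 1e-12 * abs(half) + 1e-300
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    ain <- s[k] <= eps; bin <- s[k2] <= eps
    if (ain) out <- rbind(out, poly[k, ])
    if (xor(ain, bin)) {
      t <- s[k] / (s[k] - s[k2])
      out <- rbind(out, poly[k, ] + t * (poly[k2, ] - poly[k, ]))
    }
  }
  out
}

oracle_voronoi_cell <- function(pts, box, i) {
  hw <- 0.6 * box[1]; hh <- 0.6 * box[2]
  poly <- cbind(c(-hw, hw, hw, -hw), c(-hh, -hh, hh, hh))
  for (j in seq_len(nrow(pts))) {
    for (sx in -1:1) for (sy in -1:1) {
      if (j == i && sx == 0 && sy == 0) next
      q <- c(pts[j, 1] + sx * box[1], pts[j, 2] + sy * box[2]) - pts[i, ]
      poly <- oracle_clip(poly, q[1], q[2], sum(q^2) / 2)
    }
  }
  # drop duplicate consecutive vertices
  keep <- rep(TRUE, nrow(poly))
  for (k in seq_len(nrow(poly))) {
    k2 <- if (k == nrow(poly)) 1L else k + 1L
    if (sqrt(sum((poly[k2, ] - poly[k, ])^2)) < 1e-9) keep[k2] <- FALSE
  }
  sweep(poly[keep, , drop = FALSE], 2, -pts[i, ])
}

# vertex-set comparison up to cyclic order
expect_same_vertex_set <- function(got, want, tol = 1e-8) {
  expect_equal(nrow(got), nrow(want))
  for (k in seq_len(nrow(want))) {
    d <- sqrt((got[, 1] - want[k, 1])^2 + (got[, 2] - want[k, 2])^2)
    expect_lt(min(d), tol)
  }
}

# ---- Monte-Carlo second-moment oracle ---------------------------------------
# Uniform rejection sampling in the bounding box; returns the circularity
# estimate and its standard error.

mc_circularity <- function(poly, n = 2e6) {
  bb <- apply(poly, 2, range)
  x <- stats::runif(n, bb[1, 1], bb[2, 1])
  y <- stats::runif(n, bb[1, 2], bb[2, 2])
  inside <- point_in_convex(poly, x, y)
  x <- x[inside]; y <- y[inside]
  A_bb <- diff(bb[, 1]) * diff(bb[, 2])
  A <- A_bb * mean(inside)
  cx <- mean(x); cy <- mean(y)
  r2 <- (x - cx)^2 + (y - cy)^2
  trI <- A * mean(r2)                      # area integral of r^2 about centroid
  C <- A^2 / (2 * pi * trI)
  # first-order error propagation from the spread of r^2
  rel <- stats::sd(r2) / (mean(r2) * sqrt(length(x)))
  list(C = C, sigma = C * rel)
}

point_in_convex <- function(poly, x, y) {
  # assumes CCW convex polygon
  m <- nrow(poly)
  ok <- rep(TRUE, length(x))
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    ex <- poly[k2, 1] - poly[k, 1]; ey <- poly[k2, 2] - poly[k, 2]
    ok <- ok & (ex * (y - poly[k, 2]) - ey * (x - poly[k, 1]) >= -1e-12)
  }
  ok
}

regular_polygon <- function(n, r = 1, phase = 0, center = c(0, 0)) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# ---- shared expensive fixtures ----------------------------------------------
# Built once per test session; sizes documented in the methods vignette.

.fixtures <- new.env(parent = emptyenv())

fixture_fluid_lattice <- function() {
  if (is.null(.fixtures$lat)) {
    n <- 16640                      # 416 cells of ~40 sites
    .fixtures$lat <- fluid_voronoi_lattice(n, box = rep(sqrt(n), 2),
                                           t_w = 1500, seed = 5)
  }
  .fixtures$lat
}

fixture_small_fluid_lattice <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- fluid_voronoi_lattice(1024, t_w = 500, seed = 9)
  }
  .fixtures$small
}
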