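#' Periodic polygonal lattices
#'
#' A `poly_lattice` is the static substrate on which the cellular Potts
#' dynamics runs: a periodic box tiled by convex polygonal sites, with a
#' symmetric adjacency (two sites are neighbors when their polygons share at
#' least one vertex) and a per-pair contact length `l_ij`. In edge-weighted
#' mode the surface-energy weight of a pair is `w_ij = l_ij / lbar`, where
#' `lbar` is the mean length of all distinct positive-length edges of the
#' lattice; vertex-only contacts have `l_ij = 0` and hence zero weight. In
#' uniform mode every neighbor pair has weight 1, the convention for regular
#' lattices.
#'
#' @param box numeric length-2, box dimensions `c(Lx, Ly)`.
#' @param vertices list of n x 2 matrices, one CCW vertex ring per site
#'   (a local, unwrapped copy).
#' @param neighbors list of integer vectors of neighbor site ids.
#' @param edge_lengths list of numeric vectors aligned with `neighbors`.
#' @param weight_mode `"uniform"` or `"edge-weighted"`.
#' @return An object of class `poly_lattice` with components `box`, `n_sites`,
#'   `vertices`, `centroid`, `area`, `neighbors`, `edge_lengths`,
#'   `mean_edge_length`, `weights`, `weight_mode`.
#' @keywords internal
new_poly_lattice <- function(box, vertices, neighbors, edge_lengths,
                             weight_mode = c("edge-weighted", "uniform"),
                             area = NULL, centroid = NULL) {
  weight_mode <- match.arg(weight_mode)
  n <- length(vertices)
  if (is.null(area) || is.null(centroid)) {
    geo <- lapply(vertices, polygon_geometry)
    area <- vapply(geo, `[[`, numeric(1), "area")
    centroid <- do.call(rbind, lapply(geo, `[[`, "centroid"))
  }
  lbar <- mean_edge_length(neighbors, edge_lengths)
  weights <- if (weight_mode == "edge-weighted") {
    lapply(edge_lengths, function(l) l / lbar)
  } else {
    lapply(neighbors, function(nb) rep(1, length(nb)))
  }
  lat <- structure(
    list(box = as.numeric(box), n_sites = n, vertices = vertices,
         centroid = centroid, area = as.numeric(area),
         neighbors = neighbors, edge_lengths = edge_lengths,
         mean_edge_length = lbar, weights = weights, weight_mode = weight_mode),
    class = "poly_lattice")
  validate_lattice(lat)
  lat
}

# mean over distinct undirected positive-length edges
mean_edge_length <- function(neighbors, edge_lengths) {
  src <- rep.int(seq_along(neighbors), lengths(neighbors))
  dst <- unlist(neighbors, use.names = FALSE)
  len <- unlist(edge_lengths, use.names = FALSE)
  sel <- dst > src & len > 0
  if (!any(sel)) stop("lattice has no positive-length edges")
  mean(len[sel])
}

#' Check the structural invariants of a lattice
#'
#' Verifies area conservation (site areas sum to the box area), symmetry of
#' the adjacency with consistent edge lengths, absence of self-adjacency, and
#' the weight normalization (mean weight over distinct positive-length edges
#' equals 1 in edge-weighted mode; all weights 1 in uniform mode).
#'
#' @param lattice a `poly_lattice`.
#' @param tol relative tolerance for the area and weight checks.
#' @return `lattice`, invisibly; errors describe the violated invariant.
#' @export
validate_lattice <- function(lattice, tol = 1e-8) {
  box <- lattice$box
  if (length(box) != 2 || any(!is.finite(box)) || any(box <= 0))
    stop("box dimensions must be two positive numbers")
  n <- lattice$n_sites
  if (length(lattice$neighbors) != n || length(lattice$edge_lengths) != n)
    stop("adjacency lists do not match the number of sites")
  if (any(lattice$area <= 0)) stop("all site areas must be positive")
  if (abs(sum(lattice$area) - prod(box)) > tol * prod(box))
    stop("site areas do not sum to the box area")
  deg <- lengths(lattice$neighbors)
  if (any(deg != lengths(lattice$edge_lengths)))
    stop("edge_lengths not aligned with neighbors")
  src <- rep.int(seq_len(n), deg)
  dst <- unlist(lattice$neighbors, use.names = FALSE)
  len <- unlist(lattice$edge_lengths, use.names = FALSE)
  if (length(dst) && (min(dst) < 1 || max(dst) > n))
    stop("neighbor id out of range")
  if (any(dst == src))
    stop(sprintf("site %d is listed as its own neighbor", src[which(dst == src)[1]]))
  key <- (src - 1) * n + (dst - 1)
  if (anyDuplicated(key)) {
    d <- src[which(duplicated(key))[1]]
    stop(sprintf("site %d: duplicated neighbor entry", d))
  }
  rev_pos <- match((dst - 1) * n + (src - 1), key)
  if (anyNA(rev_pos)) {
    b <- which(is.na(rev_pos))[1]
    stop(sprintf("adjacency is not symmetric: %d -> %d has no reverse entry",
                 src[b], dst[b]))
  }
  bad <- abs(len - len[rev_pos]) > 1e-9 * pmax(1, len)
  if (any(bad)) {
    b <- which(bad)[1]
    stop(sprintf("edge length mismatch between %d and %d", src[b], dst[b]))
  }
  w_all <- unlist(lattice$weights, use.names = FALSE)
  if (lattice$weight_mode == "edge-weighted") {
    sel <- dst > src & len > 0
    if (abs(mean(w_all[sel]) - 1) > tol)
      stop("mean edge weight over distinct positive-length edges is not 1")
  } else {
    if (any(w_all != 1))
      stop("uniform mode requires all weights equal to 1")
  }
  invisible(lattice)
}

#' @export
print.poly_lattice <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("poly_lattice: %d sites in a %.6g x %.6g periodic box\n",
              x$n_sites, x$box[1], x$box[2]))
  cat(sprintf("  weight mode: %s; mean edge length: %.6g\n",
              x$weight_mode, x$mean_edge_length))
  cat(sprintf("  site area: mean %.4g (cv %.3g); neighbors per site: %d-%d\n",
              mean(x$area), stats::sd(x$area) / mean(x$area), min(deg), max(deg)))
  invisible(x)
}

# area and centroid of a simple polygon (shoelace)
polygon_geometry <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  ctr <- c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
  list(area = a, centroid = ctr, perimeter = sum(sqrt((x2 - x)^2 + (y2 - y)^2)))
}

#' Build a periodic square lattice with Moore adjacency
#'
#' Unit-square sites on an `n_cols` x `n_rows` grid with spacing `spacing`.
#' Under the shared-vertex neighborhood rule each site has 8 neighbors (the
#' Moore neighborhood): 4 edge-sharing with contact length `spacing` and 4
#' corner (vertex-only) contacts with length 0. Regular lattices default to
#' uniform weights (all `w_ij = 1`).
#'
#' @param n_cols,n_rows grid dimensions, both at least 3 (smaller grids would
#'   make periodic images of a site coincide among its neighbors).
#' @param spacing side length of each square site.
#' @param weight_mode `"uniform"` (default) or `"edge-weighted"`; in the
#'   latter, corner contacts get weight 0.
#' @return A [poly_lattice][new_poly_lattice] with `n_cols * n_rows` sites.
#' @examples
#' lat <- build_square_lattice(4, 4, 1)
#' lengths(lat$neighbors)  # all 8
#' @export
build_square_lattice <- function(n_cols, n_rows, spacing = 1,
                                 weight_mode = c("uniform", "edge-weighted")) {
  weight_mode <- match.arg(weight_mode)
  if (n_cols < 3 || n_rows < 3)
    stop("n_cols and n_rows must be at least 3 for a periodic Moore adjacency")
  if (spacing <= 0) stop("spacing must be positive")
  n <- n_cols * n_rows
  ix <- rep(seq_len(n_cols) - 1L, times = n_rows)
  iy <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cx <- (ix + 0.5) * spacing
  cy <- (iy + 0.5) * spacing
  half <- spacing / 2
  vertices <- lapply(seq_len(n), function(i) {
    cbind(cx[i] + half * c(-1, 1, 1, -1), cy[i] + half * c(-1, -1, 1, 1))
  })
  id <- function(dx, dy) {
    jx <- (ix + dx) %% n_cols
    jy <- (iy + dy) %% n_rows
    as.integer(jy * n_cols + jx + 1)
  }
  sh <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
             c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  nbr_mat <- vapply(sh, function(s) id(s[1], s[2]), integer(n))
  len_row <- c(rep(spacing, 4), rep(0, 4))
  neighbors <- vector("list", n)
  edge_lengths <- vector("list", n)
  for (i in seq_len(n)) {
    o <- order(nbr_mat[i, ])
    neighbors[[i]] <- nbr_mat[i, o]
    edge_lengths[[i]] <- len_row[o]
  }
  new_poly_lattice(c(n_cols, n_rows) * spacing, vertices, neighbors,
                   edge_lengths, weight_mode,
                   area = rep(spacing^2, n), centroid = cbind(cx, cy))
}

#' Build a periodic hexagonal lattice
#'
#' Regular pointy-top hexagons of area `cell_area` tiling the box in
#' `n_rows` offset rows of `n_cols` hexagons; `n_rows` must be even for the
#' tiling to close periodically. Every site has 6 edge-sharing neighbors with
#' equal contact lengths, so edge-weighted weights are identically 1; the
#' default mode is uniform, matching the regular-lattice convention.
#'
#' The lattice is constructed as the periodic Voronoi tessellation of the
#' triangular grid of hexagon centers, which guarantees exact consistency
#' with the irregular-lattice machinery.
#'
#' @param n_cols,n_rows tiling dimensions; `n_rows` must be even.
#' @param cell_area area of each hexagonal site.
#' @param weight_mode `"uniform"` (default) or `"edge-weighted"`.
#' @return A [poly_lattice][new_poly_lattice] with `n_cols * n_rows` sites in
#'   a box `n_cols * d` x `n_rows * d * sqrt(3)/2`, where
#'   `d = sqrt(2 * cell_area / sqrt(3))` is the center spacing.
#' @export
build_hexagonal_lattice <- function(n_cols, n_rows, cell_area = 1,
                                    weight_mode = c("uniform", "edge-weighted")) {
  weight_mode <- match.arg(weight_mode)
  if (n_cols < 3 || n_rows < 3) stop("n_cols and n_rows must be at least 3")
  if (n_rows %% 2 != 0) stop("n_rows must be even for a periodic hexagonal tiling")
  if (cell_area <= 0) stop("cell_area must be positive")
  d <- sqrt(2 * cell_area / sqrt(3))     # horizontal center spacing
  v <- d * sqrt(3) / 2                   # row spacing
  box <- c(n_cols * d, n_rows * v)
  pts <- triangular_centers(n_cols, n_rows, d, v)
  lat <- build_voronoi_lattice(pts, box)
  if (weight_mode == "uniform") {
    lat$weight_mode <- "uniform"
    lat$weights <- lapply(lat$neighbors, function(nb) rep(1, length(nb)))
  }
  lat
}

# centers of a periodic triangular lattice (rows offset by half a spacing)
triangular_centers <- function(n_cols, n_rows, d, v) {
  ix <- rep(seq_len(n_cols) - 1L, times = n_rows)
  iy <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cbind((ix + 0.25 + 0.5 * (iy %% 2)) * d, (iy + 0.5) * v)
}

#' Build a lattice from the periodic Voronoi tessellation of a point set
#'
#' Each generator point gets the convex polygon of positions closer to it
#' than to any other generator (under periodic boundary conditions). Two
#' sites are neighbors when their polygons share an edge or only a vertex;
#' vertex-only contacts are kept in the adjacency with contact length 0 (they
#' allow copy attempts but carry no surface energy). If the same pair of
#' cells touches across several periodic images, the contact lengths are
#' summed into a single adjacency entry. The lattice is returned in
#' edge-weighted mode, `w_ij = l_ij / lbar`.
#'
#' @param points n x 2 matrix of generator coordinates (wrapped into the box).
#' @param box numeric length-2 box `c(Lx, Ly)`.
#' @param tol absolute coordinate tolerance used to merge near-duplicate
#'   polygon vertices and to detect shared vertices.
#' @return A [poly_lattice][new_poly_lattice] with one site per generator, in
#'   generator order.
#' @examples
#' set.seed(1)
#' pts <- cbind(runif(32, 0, 8), runif(32, 0, 8))
#' lat <- build_voronoi_lattice(pts, c(8, 8))
#' abs(sum(lat$area) - 64) < 1e-8
#' @export
build_voronoi_lattice <- function(points, box, tol = 1e-9) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  if (nrow(points) < 4) stop("at least 4 generator points are required")
  vor <- cpp_voronoi(points, box[1], box[2], tol)
  new_poly_lattice(box, vor$vertices, vor$neighbors, vor$edge_lengths,
                   "edge-weighted", area = vor$area, centroid = vor$centroid)
}

#' Save / load a lattice as JSON
#'
#' The file holds the box, the weight mode and, per site, the vertex ring,
#' neighbor ids and contact lengths at full double precision; derived
#' quantities (areas, centroids, mean edge length, weights) are recomputed on
#' load, and the loaded lattice is re-validated, so a file with, e.g., an
#' asymmetric adjacency is rejected.
#'
#' @param lattice a `poly_lattice`.
#' @param path file path.
#' @return `save_lattice` returns `path` invisibly; `load_lattice` returns
#'   the reconstructed `poly_lattice`.
#' @export
save_lattice <- function(lattice, path) {
  sites <- lapply(seq_len(lattice$n_sites), function(i) {
    list(id = i,
         vertices = unname(lattice$vertices[[i]]),
         neighbors = as.integer(lattice$neighbors[[i]]),
         edge_lengths = as.numeric(lattice$edge_lengths[[i]]))
  })
  obj <- list(box = list(Lx = lattice$box[1], Ly = lattice$box[2]),
              weight_mode = lattice$weight_mode,
              sites = sites)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_lattice
#' @export
load_lattice <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed lattice file: ", conditionMessage(e)))
  for (f in c("box", "weight_mode", "sites"))
    if (is.null(obj[[f]])) stop("malformed lattice file: missing field '", f, "'")
  if (is.null(obj$box$Lx) || is.null(obj$box$Ly))
    stop("malformed lattice file: field 'box' needs Lx and Ly")
  sites <- obj$sites
  getcol <- function(name) {
    if (is.data.frame(sites)) sites[[name]] else lapply(sites, `[[`, name)
  }
  ids <- unlist(getcol("id"))
  if (is.null(ids) || any(sort(ids) != seq_along(ids)))
    stop("malformed lattice file: field 'sites.id' must enumerate 1..n")
  ord <- order(ids)
  vertices <- lapply(getcol("vertices")[ord], function(v) {
    m <- as.matrix(v)
    if (ncol(m) != 2) stop("malformed lattice file: field 'sites.vertices' must be n x 2")
    storage.mode(m) <- "double"
    m
  })
  neighbors <- lapply(getcol("neighbors")[ord], function(x) as.integer(unlist(x)))
  edge_lengths <- lapply(getcol("edge_lengths")[ord], function(x) as.numeric(unlist(x)))
  new_poly_lattice(c(obj$box$Lx, obj$box$Ly), vertices, neighbors, edge_lengths,
                   obj$weight_mode)
}

# Flatten the adjacency to CSR arrays for the C++ engine. The per-entry
# energy weight is the lattice weight (1 in uniform mode, l/lbar otherwise).
lattice_flat <- function(lattice) {
  deg <- lengths(lattice$neighbors)
  list(nb_off = c(0L, cumsum(deg)),
       nb_id = unlist(lattice$neighbors, use.names = FALSE) - 1L,
       nb_w = unlist(lattice$weights, use.names = FALSE),
       site_area = lattice$area,
       n_sites = lattice$n_sites)
}

# minimum-image displacement
min_image <- function(d, L) d - L * round(d / L)

# wrap coordinates into [0, L)
wrap_box <- function(p, box) {
  p[, 1] <- p[, 1] %% box[1]
  p[, 2] <- p[, 2] %% box[2]
  p
}
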