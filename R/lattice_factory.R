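#' Generate cell centers of an equilibrated fluid configuration
#'
#' Runs a square-lattice cellular Potts simulation in the fluid regime
#' (default surface tension 0.8, area spring 1, kT 1) for `t_w` sweeps from
#' a rectangular 5 x 8 initialization, and returns the periodic-aware
#' centers of mass of all cells. These centers are the generators of the
#' disordered lattices: uniformly sized fluid-phase cells give a point set
#' that is locally even (no large density contrasts, unlike a Poisson
#' process) yet free of long-range orientational order.
#'
#' The box is chosen as the most nearly square integer box `5a x 8b` with
#' `a * b = n_cells` rectangles, so the site count is `A0 * n_cells`.
#'
#' @param n_cells number of fluid cells (= number of generated centers);
#'   must factor as `a * b` with aspect ratio `5a/(8b)` within `[1/3, 3]`.
#' @param A0 target cell area of the generator run (sites per cell).
#' @param alpha surface tension of the generator run; the default 0.8 is in
#'   the fluid phase.
#' @param t_w equilibration sweeps.
#' @param seed integer seed; fixed seed gives bit-identical centers.
#' @return List with `points` (n_cells x 2, wrapped into the box) and `box`.
#' @export
generate_fluid_centers <- function(n_cells, A0 = 40, alpha = 0.8,
                                   t_w = 20000L, seed = 1L) {
  if (n_cells < 16) stop("n_cells must be at least 16")
  ab <- rect_factorization(n_cells)
  lat <- build_square_lattice(5L * ab[1], 8L * ab[2], 1)
  params <- sim_params(alpha = alpha, lam = 1, A0 = A0, kT = 1, seed = seed)
  set.seed(seed)
  field <- init_rectangles(lat, 5, 8)
  if (field$n_cells != n_cells)
    stop("internal error: rectangle tiling did not produce n_cells cells")
  field <- cpm_sweep(lat, field, params, n_sweeps = t_w)$field
  if (any(field$cell_area <= 0))
    stop("degenerate fluid state: a cell reached zero area")
  pts <- wrap_box(cell_cms(lat, field), lat$box)
  list(points = pts, box = lat$box)
}

# factor n = a * b with 5a x 8b as square as possible
rect_factorization <- function(n) {
  divs <- which(n %% seq_len(n) == 0)
  a <- divs
  b <- n %/% divs
  asp <- abs(log(5 * a / (8 * b)))
  k <- which.min(asp)
  if (asp[k] > log(3))
    stop(sprintf("n_cells = %d has no factorization a x b with box aspect 5a/8b in [1/3, 3]", n))
  c(a[k], b[k])
}

#' Disordered lattice from a fluid configuration
#'
#' Convenience pipeline: [generate_fluid_centers()], rescale of the centers
#' to a target box, then [build_voronoi_lattice()]. The default target is
#' the isotropic rescale of the generator box to area `n_sites`, i.e. unit
#' mean site area with the fluid structure undistorted; passing a slightly
#' different `box` (e.g. one exactly tileable by hexagons of the intended
#' cell area) stretches the lattice by the corresponding per-axis factors,
#' so `box` should stay close to the generator's aspect ratio.
#'
#' @inheritParams generate_fluid_centers
#' @param n_sites number of lattice sites (= fluid cells of the generator).
#' @param box optional target box `c(Lx, Ly)`.
#' @return A [poly_lattice][new_poly_lattice] in edge-weighted mode, with the
#'   generator settings in attribute `"generator"`.
#' @export
fluid_voronoi_lattice <- function(n_sites, box = NULL, A0 = 40, alpha = 0.8,
                                  t_w = 20000L, seed = 1L) {
  gen <- generate_fluid_centers(n_sites, A0 = A0, alpha = alpha, t_w = t_w,
                                seed = seed)
  if (is.null(box)) box <- gen$box * sqrt(n_sites / prod(gen$box))
  pts <- cbind(gen$points[, 1] * box[1] / gen$box[1],
               gen$points[, 2] * box[2] / gen$box[2])
  lat <- build_voronoi_lattice(pts, box)
  attr(lat, "generator") <- list(n_sites = n_sites, A0 = A0, alpha = alpha,
                                 t_w = t_w, seed = seed, gen_box = gen$box)
  lat
}

#' Spectral isotropy check of a point set
#'
#' Rasterizes the points onto an `n_grid` x `n_grid` binary image, takes the
#' 2D discrete Fourier transform, and examines the power in the first
#' structure-factor ring (wavenumbers near `2 pi / u`, with
#' `u = sqrt(box area / n)` the average point spacing). The anisotropy score
#' is the coefficient of variation, across angular bins, of the
#' log-compressed ring power `log(1 + |F|^2)` (the scaling on which Fourier
#' transforms are conventionally displayed, and which keeps speckle noise
#' from dominating a sharp ring): near 0 for an isotropic ring, large when
#' the ring collapses onto Bragg peaks (e.g. a triangular crystal). A
#' quantitative stand-in for the visual inspection of the transform's rings.
#'
#' @param points n x 2 matrix (>= 100 points for a meaningful score).
#' @param box numeric length-2 periodic box.
#' @param n_grid raster resolution.
#' @param ring_band numeric length-2, ring limits in units of `2 pi / u`.
#' @param n_angular number of angular bins over half a turn (the spectrum of
#'   a real image is centro-symmetric).
#' @return List with `radial_profile` (data frame `k_rel`, `intensity`;
#'   wavenumber in units of `2 pi / u`), `anisotropy_score`, `u`,
#'   `ring_band`.
#' @export
isotropy_check <- function(points, box, n_grid = 512, ring_band = c(0.7, 1.3),
                           n_angular = 36) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 100) stop("need at least 100 points for a meaningful score")
  if (ring_band[2] <= ring_band[1]) stop("empty ring band")
  u <- sqrt(prod(box) / n)
  img <- matrix(0, n_grid, n_grid)
  ix <- pmin(n_grid - 1L, floor(points[, 1] %% box[1] / box[1] * n_grid)) + 1L
  iy <- pmin(n_grid - 1L, floor(points[, 2] %% box[2] / box[2] * n_grid)) + 1L
  img[cbind(ix, iy)] <- 1
  P <- Mod(stats::fft(img))^2
  fx <- c(0:(n_grid %/% 2), -((n_grid - n_grid %/% 2 - 1):1))
  kx <- 2 * pi * fx / box[1]
  ky <- 2 * pi * fx / box[2]
  KX <- matrix(kx, n_grid, n_grid)
  KY <- matrix(ky, n_grid, n_grid, byrow = TRUE)
  kmag <- sqrt(KX^2 + KY^2)
  k0 <- 2 * pi / u
  krel <- kmag / k0

  kmaxrel <- min(max(abs(kx)), max(abs(ky))) / k0
  rbreaks <- seq(0, kmaxrel, by = 0.05)
  rbin <- findInterval(krel, rbreaks, rightmost.closed = TRUE)
  keep <- krel > 0 & krel <= kmaxrel
  prof <- tapply(P[keep], rbin[keep], mean)
  radial <- data.frame(k_rel = rbreaks[as.integer(names(prof))] + 0.025,
                       intensity = as.numeric(prof))

  in_ring <- krel >= ring_band[1] & krel <= ring_band[2]
  if (!any(in_ring)) stop("empty ring band at this raster resolution")
  th <- atan2(KY[in_ring], KX[in_ring]) %% pi
  abin <- pmin(n_angular, floor(th / pi * n_angular) + 1L)
  amean <- tapply(log1p(P[in_ring]), abin, mean)
  score <- stats::sd(amean) / mean(amean)
  list(radial_profile = radial, anisotropy_score = unname(score), u = u,
       ring_band = ring_band)
}
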