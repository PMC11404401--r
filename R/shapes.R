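#' Isoperimetric quotient
#'
#' `q = sqrt(4 pi A) / P`: 1 for a disk, close to 0 for highly elongated
#' shapes, scale invariant. The classical dimensionless ratio `4 pi A / P^2`
#' is `q^2` in this convention and is available as `iso_quotient(...)^2`.
#'
#' @param A polygon area(s), positive.
#' @param P polygon perimeter(s), positive.
#' @return Numeric vector of quotients.
#' @export
iso_quotient <- function(A, P) {
  if (any(A <= 0) || any(P <= 0)) stop("area and perimeter must be positive")
  sqrt(4 * pi * A) / P
}

#' Isoperimetric quotient of a regular polygon with a real number of edges
#'
#' For a regular `n`-gon with circumradius `r`, `A = (n/2) r^2 sin(2 pi/n)`
#' and `P = 2 n r sin(pi/n)`, so
#' \deqn{q_{reg}(n) = \frac{\sqrt{2\pi n \sin(2\pi/n)}}{2 n \sin(\pi/n)},}
#' independent of `r`, strictly increasing in `n`, and -> 1 as n -> Inf.
#' The right-hand side is well defined for non-integer `n`, which defines
#' the generalized edge number scale.
#'
#' @param n number of edges, real, `>= 3`.
#' @return `q_reg(n)`, vectorized over `n`.
#' @examples
#' round(q_reg(5), 3)  # 0.930
#' round(q_reg(6), 3)  # 0.952
#' @export
q_reg <- function(n) {
  if (any(n < 3)) stop("n must be at least 3")
  sqrt(2 * pi * n * sin(2 * pi / n)) / (2 * n * sin(pi / n))
}

#' Generalized edge number from an isoperimetric quotient
#'
#' Numerically inverts [q_reg()]: the unique `n* >= 3` with
#' `q_reg(n*) = q`. Values below `q_reg(3)` are clamped to 3 with a warning;
#' `q >= 1` is an error (no polygon attains the disk value).
#'
#' @param q isoperimetric quotient(s) in `[q_reg(3), 1)`.
#' @param tol absolute tolerance on `q` for the root search.
#' @return `n*`, vectorized over `q`.
#' @export
n_star <- function(q, tol = 1e-12) {
  if (any(q >= 1)) stop("q must be below 1 (disk limit)")
  q3 <- q_reg(3)
  low <- q < q3
  if (any(low)) {
    warning(sprintf("%d value(s) below q_reg(3) = %.6f clamped to n* = 3",
                    sum(low), q3))
    q[low] <- q3
  }
  vapply(q, function(qi) {
    if (qi <= q3) return(3)
    hi <- 6
    while (q_reg(hi) < qi) hi <- hi * 2
    stats::uniroot(function(n) q_reg(n) - qi, c(3, hi), tol = 1e-12,
                   f.lower = q3 - qi)$root
  }, numeric(1))
}

#' Second moments of area and circularity of a polygon
#'
#' `polygon_moments` evaluates the area, centroid and centroidal second
#' moment-of-area tensor of a simple polygon from the closed-form shoelace
#' expressions. `circularity` is the Hu-moment roundness
#' \deqn{C = \frac{A^2}{2\pi\,\mathrm{tr}(\bar I)},}
#' with `tr(Ibar)` the trace of the centroidal second-moment tensor: 1 for a
#' disk, invariant under translation, rotation and uniform scaling.
#'
#' @param polygon m x 2 matrix of vertices (either orientation).
#' @return `polygon_moments`: list with `area`, `centroid`, `Ixx`, `Iyy`,
#'   `trace` (about the centroid). `circularity`: scalar `C` in `(0, 1]`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' circularity(sq) * pi  # 3
#' @export
polygon_moments <- function(polygon) {
  v <- as.matrix(polygon)
  if (nrow(v) < 3) stop("degenerate polygon")
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  s <- sign(A)
  if (A == 0) stop("degenerate polygon (zero area)")
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum(cr * (y^2 + y * y2 + y2^2)) / 12   # integral of y^2 dA
  Iyy <- sum(cr * (x^2 + x * x2 + x2^2)) / 12
  A <- abs(A); Ixx <- s * Ixx; Iyy <- s * Iyy
  Ixx <- Ixx - A * cy^2
  Iyy <- Iyy - A * cx^2
  list(area = A, centroid = c(cx, cy), Ixx = Ixx, Iyy = Iyy, trace = Ixx + Iyy)
}

#' @rdname polygon_moments
#' @export
circularity <- function(polygon) {
  m <- polygon_moments(polygon)
  if (m$trace <= 0) stop("degenerate polygon")
  m$area^2 / (2 * pi * m$trace)
}

#' Circularity of a regular polygon with a real number of edges
#'
#' Closed form from the regular-polygon second moments
#' (`J = n r^4 sin(2 pi/n) (2 + cos(2 pi/n)) / 12` about the centroid):
#' \deqn{C_{reg}(n) = \frac{3 n \sin(2\pi/n)}{2\pi\,(2+\cos(2\pi/n))},}
#' strictly increasing in `n` and -> 1 as n -> Inf. `c_pentagon()` returns
#' the regular-pentagon value `C(5)`, the reference used by the
#' transition indicator based on the mode of the circularity distribution.
#'
#' @param n number of edges, real, `>= 3`.
#' @return `C_reg(n)`, vectorized.
#' @export
c_reg <- function(n) {
  if (any(n < 3)) stop("n must be at least 3")
  3 * n * sin(2 * pi / n) / (2 * pi * (2 + cos(2 * pi / n)))
}

#' @rdname c_reg
#' @export
c_pentagon <- function() c_reg(5)

#' Circularity-derived generalized edge number
#'
#' Inverts [c_reg()] by bracketed root finding; values below `C_reg(3)` are
#' clamped to 3 with a warning, `C >= 1` is an error.
#'
#' @param C circularity value(s) in `[C_reg(3), 1)`.
#' @return `n°`, vectorized over `C`.
#' @export
n_circ <- function(C) {
  if (any(C >= 1)) stop("C must be below 1 (disk limit)")
  c3 <- c_reg(3)
  low <- C < c3
  if (any(low)) {
    warning(sprintf("%d value(s) below C_reg(3) = %.6f clamped to 3", sum(low), c3))
    C[low] <- c3
  }
  vapply(C, function(ci) {
    if (ci <= c3) return(3)
    hi <- 6
    while (c_reg(hi) < ci) hi <- hi * 2
    stats::uniroot(function(n) c_reg(n) - ci, c(3, hi), tol = 1e-12,
                   f.lower = c3 - ci)$root
  }, numeric(1))
}

#' Voronoi shapes of cell centers
#'
#' Periodic Voronoi tessellation of the cell centers, the standard route to
#' lattice-independent cell shapes: lattice-based borders are jagged
#' (perimeters are metric-inflated), so areas and perimeters are measured on
#' the Voronoi polygons of the centers instead.
#'
#' @param centers n x 2 matrix of cell centers (>= 4, distinct under minimum
#'   image).
#' @param box numeric length-2 periodic box.
#' @return Data frame with one row per center: `cell`, `A`, `P`, `q_v`,
#'   `n_star`, `C_v`; polygons are attached as attribute `"polygons"`.
#' @export
voronoi_shapes <- function(centers, box) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 4) stop("at least 4 centers are required")
  vor <- cpp_voronoi(centers, box[1], box[2], 1e-9)
  qv <- iso_quotient(vor$area, vor$perimeter)
  cv <- vapply(vor$vertices, circularity, numeric(1))
  out <- data.frame(cell = seq_len(nrow(centers)), A = vor$area,
                    P = vor$perimeter, q_v = qv,
                    n_star = suppressWarnings(n_star(pmin(qv, 1 - 1e-12))),
                    C_v = cv)
  attr(out, "polygons") <- vor$vertices
  out
}

#' Fractions of pseudo-polygons
#'
#' Bins generalized edge numbers by nearest integer with an upper-inclusive
#' rule (`n - 0.5 < n* <= n + 0.5`; e.g. pseudo-pentagons are
#' `4.5 < n* <= 5.5`) and returns the fraction in each class.
#'
#' @param n_star_values numeric vector of generalized edge numbers.
#' @param classes integer classes to report (default 3:9; values outside are
#'   counted in the extreme classes' complement and still enter the total).
#' @return Data frame with columns `n`, `count`, `fraction`; fractions sum
#'   to 1 over all occupied classes.
#' @export
pseudo_fractions <- function(n_star_values, classes = 3:9) {
  if (!length(n_star_values)) stop("empty value list")
  cls <- ceiling(n_star_values - 0.5)  # n - 0.5 < x <= n + 0.5
  all_cls <- sort(unique(c(classes, cls)))
  cnt <- vapply(all_cls, function(k) sum(cls == k), numeric(1))
  data.frame(n = all_cls, count = cnt, fraction = cnt / length(n_star_values))
}

#' Histogram summary with fitted extrema
#'
#' Density-normalized histogram with per-bin standard errors, the position
#' of the dominant mode(s) refined by a local quadratic fit over
#' `fit_halfwidth` bins on each side, and — when the distribution is
#' bimodal — the interior local minimum between the two modes. Bimodality is
#' decided by persistence: a secondary local maximum counts as a genuine
#' mode when its height exceeds the valley between the two candidate modes
#' by more than `2 x` its bin standard error.
#'
#' @param values numeric sample (>= 100 values).
#' @param n_bins number of histogram bins over the data range.
#' @param fit_halfwidth half-width, in bins, of the quadratic refinement.
#' @return List with `mids`, `density`, `sem`, `peaks` (1 or 2 refined
#'   positions, decreasing height), `peak_heights`, `minimum` (refined
#'   position, or `NA` when unimodal), `bimodal`.
#' @export
distribution_summary <- function(values, n_bins = 60, fit_halfwidth = 3) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need at least 100 values")
  rng <- range(values)
  if (diff(rng) == 0)
    return(list(mids = rng[1], density = Inf, sem = 0, peaks = rng[1],
                peak_heights = Inf, minimum = NA_real_, bimodal = FALSE))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  dens <- h$density
  bw <- diff(breaks)[1]
  ntot <- length(values)
  sem <- sqrt(pmax(h$counts, 1)) / (ntot * bw)

  refine <- function(k, what = c("max", "min")) {
    what <- match.arg(what)
    idx <- max(1, k - fit_halfwidth):min(n_bins, k + fit_halfwidth)
    if (length(idx) < 3) return(h$mids[k])
    fit <- stats::lm(d ~ m + I(m^2), data = data.frame(m = h$mids[idx], d = dens[idx]))
    cf <- stats::coef(fit)
    ok <- if (what == "max") cf[3] < 0 else cf[3] > 0
    pos <- if (ok && is.finite(cf[3]) && cf[3] != 0) -cf[2] / (2 * cf[3]) else h$mids[k]
    if (pos < h$mids[idx[1]] || pos > h$mids[idx[length(idx)]]) h$mids[k] else unname(pos)
  }

  # strict-ish local maxima (plateaus resolved to their first bin)
  is_max <- vapply(seq_len(n_bins), function(k) {
    l <- if (k > 1) dens[k - 1] else -Inf
    r <- if (k < n_bins) dens[k + 1] else -Inf
    dens[k] > l && dens[k] >= r
  }, logical(1))
  cand <- which(is_max)
  if (!length(cand)) cand <- which.max(dens)
  cand <- cand[order(-dens[cand])]

  top <- cand[1]
  bimodal <- FALSE
  second <- NA_integer_
  vall <- NA_integer_
  for (k in cand[-1]) {
    lo <- min(top, k); hi <- max(top, k)
    if (hi - lo < 2) next
    v <- lo + which.min(dens[(lo + 1):(hi - 1)])
    if (dens[k] - dens[v] > 2 * sem[k]) {
      bimodal <- TRUE; second <- k; vall <- v
      break
    }
  }
  if (bimodal) {
    peaks <- c(refine(top, "max"), refine(second, "max"))
    list(mids = h$mids, density = dens, sem = sem, peaks = peaks,
         peak_heights = dens[c(top, second)], minimum = refine(vall, "min"),
         bimodal = TRUE)
  } else {
    list(mids = h$mids, density = dens, sem = sem, peaks = refine(top, "max"),
         peak_heights = dens[top], minimum = NA_real_, bimodal = FALSE)
  }
}
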