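#' Periodic-aware centers of mass of all cells
#'
#' Area-weighted centroid of each cell's member sites, computed with
#' minimum-image displacements relative to a per-cell reference point (the
#' cell's previous center when tracking a trajectory, else the centroid of
#' the cell's first member site). With a reference the output is continuous
#' in time across periodic boundaries (unwrapped) for cells smaller than
#' half the box.
#'
#' @inheritParams total_energy
#' @param prev_positions optional n_cells x 2 matrix of previous (unwrapped)
#'   centers used as references.
#' @return n_cells x 2 matrix of center-of-mass positions.
#' @export
cell_cms <- function(lattice, field, prev_positions = NULL) {
  nc <- field$n_cells
  if (any(tabulate(field$spin, nc) == 0)) stop("empty cell in spin field")
  if (is.null(prev_positions)) {
    first <- match(seq_len(nc), field$spin)
    ref <- lattice$centroid[first, , drop = FALSE]
  } else {
    ref <- as.matrix(prev_positions)
    if (nrow(ref) != nc) stop("prev_positions must have one row per cell")
  }
  dx <- min_image(lattice$centroid[, 1] - ref[field$spin, 1], lattice$box[1])
  dy <- min_image(lattice$centroid[, 2] - ref[field$spin, 2], lattice$box[2])
  w <- lattice$area
  sw <- as.numeric(rowsum(w, field$spin))
  out <- ref + cbind(as.numeric(rowsum(w * dx, field$spin)),
                     as.numeric(rowsum(w * dy, field$spin))) / sw
  dimnames(out) <- NULL
  out
}

#' Mean-squared displacement from a single time origin
#'
#' Squared displacement of every cell from its position at the origin sample
#' (the start of the sampling phase, i.e. after the waiting time), averaged
#' over cells, with the standard error of the mean across cells.
#'
#' @param trajectory a `cpm_trajectory` from [run_cpm()], or any list with
#'   `times` and a samples x cells x 2 `cms` array.
#' @param origin index of the origin sample (default 1, the sample taken at
#'   the end of equilibration).
#' @return Data frame with columns `t` (sweeps since the origin), `msd`,
#'   `sem`.
#' @export
msd <- function(trajectory, origin = 1L) {
  cms <- trajectory$cms
  nt <- dim(cms)[1]
  if (origin < 1 || origin > nt) stop("origin beyond trajectory")
  if (nt - origin < 1) stop("need at least 2 samples after the origin")
  r0x <- cms[origin, , 1]; r0y <- cms[origin, , 2]
  idx <- origin:nt
  r2 <- sapply(idx, function(s) (cms[s, , 1] - r0x)^2 + (cms[s, , 2] - r0y)^2)
  if (is.null(dim(r2))) r2 <- matrix(r2, nrow = 1)
  nc <- dim(cms)[2]
  data.frame(t = trajectory$times[idx] - trajectory$times[origin],
             msd = colMeans(r2),
             sem = apply(r2, 2, stats::sd) / sqrt(nc))
}

#' Diffusion exponent and effective diffusion coefficient from an MSD table
#'
#' Fits the power law `<r^2> ~ t^beta` by least squares on log-log axes over
#' a lag window (default: the last decade of lag times, capturing the
#' long-time behavior). The effective diffusion coefficient is the window
#' mean of `<r^2>/(4 t)`; it is reported only when the dynamics is
#' diffusive, i.e. when `|beta - 1| <= max(beta_gate, SE(beta))`.
#'
#' @param msd_table data frame with columns `t`, `msd` (and optionally `sem`)
#'   as returned by [msd()].
#' @param fit_window numeric length-2 `c(t_min, t_max)`; default
#'   `c(max(t)/10, max(t))`.
#' @param beta_gate absolute departure of beta from 1 below which the
#'   diffusive interpretation (and hence `D_eff`) is accepted.
#' @return List with `beta`, `beta_err` (standard error), `D_eff` (`NA` when
#'   the gate fails), `fit_window`, `n_lags`.
#' @export
fit_beta_deff <- function(msd_table, fit_window = NULL, beta_gate = 0.05) {
  tab <- msd_table[msd_table$t > 0, , drop = FALSE]
  if (is.null(fit_window)) fit_window <- c(max(tab$t) / 10, max(tab$t))
  tab <- tab[tab$t >= fit_window[1] & tab$t <= fit_window[2], , drop = FALSE]
  if (nrow(tab) < 5) stop("fit window must contain at least 5 lags")
  if (any(tab$msd <= 0)) stop("non-positive MSD values in the fit window")
  fit <- stats::lm(log(msd) ~ log(t), data = tab)
  beta <- unname(stats::coef(fit)[2])
  beta_err <- unname(summary(fit)$coefficients[2, 2])
  gate <- abs(beta - 1) <= max(beta_gate, beta_err)
  list(beta = beta, beta_err = beta_err,
       D_eff = if (gate) mean(tab$msd / (4 * tab$t)) else NA_real_,
       fit_window = fit_window, n_lags = nrow(tab))
}

#' Hexatic bond-orientational order parameter
#'
#' For each cell `k`, the set of neighbors is its 6 nearest centers under
#' minimum-image distance (ties broken deterministically by (distance, id)),
#' and
#' \deqn{\psi_6(k) = \frac{1}{6} \sum_{j} e^{6 i \theta(j,k)},}
#' with `theta(j,k)` the counter-clockwise angle between the x-axis and the
#' vector from center `k` to center `j`. `|psi6| = 1` for a perfect
#' hexagonal arrangement and decreases with disorder.
#'
#' @param centers n x 2 matrix of cell centers (at least 7).
#' @param box numeric length-2 periodic box.
#' @return List with `psi6` (complex per cell), `abs_psi6`, `mean_abs`
#'   (average of `|psi6|` over cells) and `sem`.
#' @export
psi6 <- function(centers, box) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 7) stop("psi6 needs at least 7 centers")
  p <- cpp_psi6(centers, box[1], box[2])
  a <- Mod(p)
  list(psi6 = p, abs_psi6 = a, mean_abs = mean(a),
       sem = stats::sd(a) / sqrt(length(a)))
}

#' Wrapped cell centers of a trajectory sample
#'
#' @param trajectory a `cpm_trajectory`.
#' @param sample sample index (default: last).
#' @return n_cells x 2 matrix of centers wrapped into the box.
#' @export
traj_centers <- function(trajectory, sample = dim(trajectory$cms)[1]) {
  wrap_box(trajectory$cms[sample, , , drop = TRUE], trajectory$box)
}
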