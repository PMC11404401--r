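#' Simulation parameters for the cellular Potts dynamics
#'
#' Bundles the physical parameters of the Hamiltonian
#' \deqn{H = \alpha \sum_{(i,j)} w_{ij} (1 - \delta_{\sigma(i)\sigma(j)})
#'       + \lambda \sum_\sigma (a_\sigma - A_0)^2}
#' (each unordered neighbor pair counted once) together with the run
#' protocol. Time is measured in Monte-Carlo sweeps (MCS), one sweep being
#' `n_sites` attempts.
#'
#' @param alpha surface tension: energy per unit weighted contact between
#'   unlike cells.
#' @param lam area-spring strength (energy per squared area unit).
#' @param A0 target cell area.
#' @param kT thermal energy scale of the Metropolis rule (default 1).
#' @param seed integer seed for the run's single random generator.
#' @param t_w equilibration (waiting) sweeps before sampling.
#' @param t_s sampling sweeps.
#' @param sample_every sweeps between recorded samples.
#' @return A `sim_params` list.
#' @export
sim_params <- function(alpha, lam = 1, A0 = 40, kT = 1, seed = 1L,
                       t_w = 0L, t_s = 0L, sample_every = 1L) {
  stopifnot(alpha > 0, lam > 0, A0 > 0, kT > 0, t_w >= 0, t_s >= 0,
            sample_every >= 1)
  structure(list(alpha = alpha, lam = lam, A0 = A0, kT = kT,
                 seed = as.integer(seed), t_w = as.integer(t_w),
                 t_s = as.integer(t_s), sample_every = as.integer(sample_every)),
            class = "sim_params")
}

#' Cell configuration on a lattice
#'
#' A `spin_field` maps every lattice site to a cell id (confluency: each site
#' belongs to exactly one cell) and carries the incrementally maintained cell
#' areas `a_sigma`.
#'
#' @param lattice a `poly_lattice`.
#' @param spin integer vector, `spin[i]` is the cell of site `i`, in
#'   `1..n_cells` with every cell non-empty.
#' @return A `spin_field` with components `spin`, `cell_area`, `n_cells`.
#' @export
spin_field <- function(lattice, spin) {
  spin <- as.integer(spin)
  if (length(spin) != lattice$n_sites)
    stop("spin must assign a cell to every lattice site")
  n_cells <- max(spin)
  if (min(spin) < 1 || length(unique(spin)) != n_cells)
    stop("cell ids must be dense in 1..n_cells with no empty cell")
  ca <- as.numeric(rowsum(lattice$area, spin))
  structure(list(spin = spin, cell_area = ca, n_cells = n_cells),
            class = "spin_field")
}

#' @export
print.spin_field <- function(x, ...) {
  cat(sprintf("spin_field: %d cells on %d sites; cell area %.4g +- %.2g\n",
              x$n_cells, length(x$spin), mean(x$cell_area), stats::sd(x$cell_area)))
  invisible(x)
}

# recompute cell areas from scratch (used by invariants/tests)
recompute_areas <- function(lattice, field) {
  out <- numeric(field$n_cells)
  agg <- rowsum(lattice$area, field$spin)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Total energy of a configuration
#'
#' Surface term: `alpha * sum w_ij` over distinct neighbor pairs with unlike
#' spins (each unordered pair counted once). Area term:
#' `lam * sum (a_sigma - A0)^2`.
#'
#' @param lattice a `poly_lattice`.
#' @param field a `spin_field` on that lattice.
#' @param params a [sim_params()].
#' @return List with `surface`, `area` and `total = surface + area`.
#' @export
total_energy <- function(lattice, field, params) {
  spin <- field$spin
  if (length(spin) != lattice$n_sites) stop("field does not match lattice")
  surf <- 0
  for (i in seq_len(lattice$n_sites)) {
    nb <- lattice$neighbors[[i]]
    sel <- nb > i
    if (any(sel))
      surf <- surf + sum(lattice$weights[[i]][sel] * (spin[nb[sel]] != spin[i]))
  }
  surface <- params$alpha * surf
  area <- params$lam * sum((field$cell_area - params$A0)^2)
  list(surface = surface, area = area, total = surface + area)
}

#' Energy change of a single spin copy
#'
#' Returns `E_new - E_old` for setting `spin[site] <- new_spin`, computed
#' locally from the site's adjacency and the two affected cell areas. This
#' equals the difference of [total_energy()] before and after the move (the
#' engine's core contract, property-tested).
#'
#' @inheritParams total_energy
#' @param site lattice site id.
#' @param new_spin invading cell id; must differ from the current spin.
#' @return Energy difference (scalar).
#' @export
delta_energy <- function(lattice, field, params, site, new_spin) {
  if (field$spin[site] == new_spin)
    stop("new_spin equals the current spin of the site (same-spin picks are no-ops)")
  if (new_spin < 1 || new_spin > field$n_cells) stop("unknown cell id")
  fl <- lattice_flat(lattice)
  cpp_delta_energy(fl$nb_off, fl$nb_id, fl$nb_w, fl$site_area,
                   field$spin, field$cell_area, site, new_spin,
                   params$alpha, params$lam, params$A0)
}

#' One Metropolis attempt
#'
#' Picks a candidate site uniformly among all sites, an invading site
#' uniformly from its full neighbor list, and — when the spins differ —
#' accepts the copy with probability `min(1, exp(-dE/kT))`. Same-spin picks
#' consume the attempt (they define the MCS clock) but change nothing.
#'
#' @inheritParams total_energy
#' @param commit if `FALSE`, the move is proposed and judged but the state is
#'   not modified (useful to probe the acceptance rule).
#' @return List with `field` (updated when `commit`), `site`, `invader`,
#'   `same_spin`, `delta_e` (`NA` for same-spin picks) and `accepted`.
#' @export
cpm_attempt <- function(lattice, field, params, commit = TRUE) {
  fl <- lattice_flat(lattice)
  res <- cpp_cpm_attempt(fl$nb_off, fl$nb_id, fl$nb_w, fl$site_area,
                         field$spin, field$cell_area,
                         params$alpha, params$lam, params$A0, params$kT, commit)
  field$spin <- res$spin
  field$cell_area <- res$cell_area
  list(field = field, site = res$site, invader = res$invader,
       same_spin = res$same_spin, delta_e = res$delta_e,
       accepted = res$accepted)
}

#' Run Monte-Carlo sweeps
#'
#' Performs `n_sweeps` sweeps of `n_sites` attempts each and returns the
#' updated field plus the per-sweep accepted-move counts.
#'
#' @inheritParams total_energy
#' @param n_sweeps number of sweeps.
#' @return List with `field` and integer vector `accepted`.
#' @export
cpm_sweep <- function(lattice, field, params, n_sweeps = 1L) {
  fl <- lattice_flat(lattice)
  res <- cpp_cpm_sweeps(fl$nb_off, fl$nb_id, fl$nb_w, fl$site_area,
                        field$spin, field$cell_area,
                        params$alpha, params$lam, params$A0, params$kT,
                        as.integer(n_sweeps))
  field$spin <- res$spin
  field$cell_area <- res$cell_area
  list(field = field, accepted = res$accepted)
}

#' Initialize cells as a rectangular tiling
#'
#' Tiles the box with `round(Lx/cell_w)` x `round(Ly/cell_h)` rectangles
#' (stretched to fit the box exactly) and assigns every site to the rectangle
#' containing its centroid. Empty rectangles are dropped and cell ids
#' renumbered densely, so the result is confluent by construction.
#'
#' @param lattice a `poly_lattice`.
#' @param cell_w,cell_h nominal rectangle dimensions (the standard
#'   disordered start uses 5 x 8).
#' @return A [spin_field()].
#' @export
init_rectangles <- function(lattice, cell_w = 5, cell_h = 8) {
  box <- lattice$box
  ncx <- max(1L, round(box[1] / cell_w))
  ncy <- max(1L, round(box[2] / cell_h))
  if (ncx * ncy < 2) stop("box too small: fewer than 2 cells")
  ix <- pmin(ncx - 1L, floor(lattice$centroid[, 1] %% box[1] / (box[1] / ncx)))
  iy <- pmin(ncy - 1L, floor(lattice$centroid[, 2] %% box[2] / (box[2] / ncy)))
  raw <- iy * ncx + ix + 1L
  spin <- match(raw, sort(unique(raw)))
  if (length(unique(spin)) < 2) stop("box too small: fewer than 2 cells")
  spin_field(lattice, spin)
}

#' Initialize cells as a hexagonal crystal
#'
#' Assigns every site to the nearest center of a periodic triangular lattice
#' of `round(Lx/d)` x `round(Ly/v)` hexagon centers (`d`, `v` the ideal
#' center and row spacings for hexagons of area `A0`), giving an ordered
#' crystalline start for high-surface-tension runs. The box must be tileable
#' within a small distortion: the realized spacings may deviate from the
#' ideal aspect ratio `sqrt(3)/2` and cell area `A0` by at most
#' `max_distortion`, otherwise an error reports the nearest tileable box.
#'
#' @param lattice a `poly_lattice`.
#' @param A0 target cell area.
#' @param max_distortion maximum relative deviation of the realized tiling
#'   from regular hexagons of area `A0`.
#' @return A [spin_field()] whose cell centers form a (slightly stretched)
#'   triangular lattice; for an undistorted box, `|psi6| = 1` for every cell.
#' @export
init_hex_cells <- function(lattice, A0, max_distortion = 0.03) {
  box <- lattice$box
  d_ideal <- sqrt(2 * A0 / sqrt(3))
  v_ideal <- d_ideal * sqrt(3) / 2
  ncx <- max(3L, round(box[1] / d_ideal))
  ncy <- max(4L, 2L * round(box[2] / v_ideal / 2))
  d <- box[1] / ncx
  v <- box[2] / ncy
  disto <- max(abs(d * v / (d_ideal * v_ideal) - 1), abs((v / d) / (sqrt(3) / 2) - 1))
  if (disto > max_distortion)
    stop(sprintf(paste0("box %.6g x %.6g is not hex-tileable for A0 = %.6g ",
                        "(distortion %.3g); nearest tileable box: %.6g x %.6g"),
                 box[1], box[2], A0, disto, ncx * d_ideal, ncy * v_ideal))
  centers <- triangular_centers(ncx, ncy, d, v)
  spin <- nearest_center(lattice$centroid, centers, box)
  spin_field(lattice, spin)
}

# nearest center under minimum image, via a coarse candidate search
nearest_center <- function(pts, centers, box) {
  n <- nrow(pts)
  m <- nrow(centers)
  spin <- integer(n)
  # for moderate m an n x m distance computation is fine and simple
  dx <- outer(pts[, 1], centers[, 1], "-")
  dy <- outer(pts[, 2], centers[, 2], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  max.col(-(dx * dx + dy * dy), ties.method = "first")
}

#' Connected components of every cell
#'
#' Counts, for each cell, the connected components of its site set under the
#' positive-contact-length adjacency (vertex-only contacts do not connect).
#' A healthy confluent configuration has exactly one component per cell;
#' fragmentation is reported, not forbidden (no connectivity constraint is
#' imposed on the dynamics).
#'
#' @inheritParams total_energy
#' @return Integer vector of component counts, one per cell.
#' @export
fragmentation_report <- function(lattice, field) {
  n <- lattice$n_sites
  spin <- field$spin
  comp <- integer(field$n_cells)
  seen <- logical(n)
  for (start in seq_len(n)) {
    if (seen[start]) next
    cell <- spin[start]
    comp[cell] <- comp[cell] + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- lattice$neighbors[[i]]
      nb <- nb[lattice$edge_lengths[[i]] > 0]
      nb <- nb[!seen[nb] & spin[nb] == cell]
      if (length(nb)) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  comp
}

#' Run the cellular Potts dynamics and record a trajectory
#'
#' Seeds the run's random generator from `params$seed`, performs `t_w`
#' equilibration sweeps, then `t_s` sampling sweeps, recording the unwrapped
#' per-cell centers of mass every `sample_every` sweeps (the sample at the
#' start of sampling is the origin for mean-squared displacements). Full
#' spin snapshots can be stored at a coarser stride.
#'
#' @inheritParams total_energy
#' @param snapshot_every store a full spin snapshot every this many sweeps of
#'   the sampling phase (0 = record only the initial and final snapshots).
#' @param observer optional function `(sweep, field, cms)` called at every
#'   sample.
#' @param strict if `TRUE` (default) abort when a cell evaporates (area 0);
#'   otherwise warn.
#' @return A `cpm_trajectory`: `times` (sweeps, 0 = start of sampling), `cms`
#'   (samples x cells x 2 array of unwrapped centers), `snapshots` (list of
#'   `list(sweep, spin)`), `field` (final state), `params`, `acceptance`
#'   (mean accepted fraction per attempt), `box`.
#' @export
run_cpm <- function(lattice, field, params, snapshot_every = 0L,
                    observer = NULL, strict = TRUE) {
  set.seed(params$seed)
  fl <- lattice_flat(lattice)
  step <- params$sample_every
  check_alive <- function(f) {
    if (any(f$cell_area <= 0)) {
      msg <- sprintf("cell evaporated (%d cells with zero area)",
                     sum(f$cell_area <= 0))
      if (strict) stop(msg) else warning(msg)
    }
  }
  sweep_chunk <- function(f, n) {
    if (n == 0) return(list(field = f, accepted = integer(0)))
    res <- cpp_cpm_sweeps(fl$nb_off, fl$nb_id, fl$nb_w, fl$site_area,
                          f$spin, f$cell_area, params$alpha, params$lam,
                          params$A0, params$kT, as.integer(n))
    f$spin <- res$spin
    f$cell_area <- res$cell_area
    list(field = f, accepted = res$accepted)
  }

  acc_total <- 0
  r <- sweep_chunk(field, params$t_w)
  field <- r$field
  acc_total <- acc_total + sum(as.numeric(r$accepted))
  check_alive(field)

  n_samp <- if (params$t_s > 0) params$t_s %/% step else 0L
  cms <- array(NA_real_, dim = c(n_samp + 1L, field$n_cells, 2L))
  times <- c(0L, if (n_samp > 0) seq_len(n_samp) * step)
  pos <- cell_cms(lattice, field)
  cms[1, , ] <- pos
  snapshots <- list(list(sweep = 0L, spin = field$spin))
  if (!is.null(observer)) observer(0L, field, pos)

  if (n_samp > 0) {
    for (s in seq_len(n_samp)) {
      r <- sweep_chunk(field, step)
      field <- r$field
      acc_total <- acc_total + sum(as.numeric(r$accepted))
      check_alive(field)
      pos <- cell_cms(lattice, field, prev_positions = pos)
      cms[s + 1L, , ] <- pos
      if (snapshot_every > 0 && (s * step) %% snapshot_every == 0)
        snapshots[[length(snapshots) + 1L]] <- list(sweep = s * step, spin = field$spin)
      if (!is.null(observer)) observer(s * step, field, pos)
    }
    # leftover sweeps that do not fill a sample interval
    rest <- params$t_s - n_samp * step
    if (rest > 0) {
      r <- sweep_chunk(field, rest)
      field <- r$field
      acc_total <- acc_total + sum(as.numeric(r$accepted))
    }
  }
  last <- snapshots[[length(snapshots)]]
  if (!identical(last$spin, field$spin))
    snapshots[[length(snapshots) + 1L]] <- list(sweep = params$t_s, spin = field$spin)

  total_attempts <- as.numeric(params$t_w + params$t_s) * lattice$n_sites
  structure(list(times = times, cms = cms, snapshots = snapshots, field = field,
                 params = params,
                 acceptance = if (total_attempts > 0) acc_total / total_attempts else NA_real_,
                 box = lattice$box),
            class = "cpm_trajectory")
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  cat(sprintf("cpm_trajectory: %d cells, %d samples (t = %d..%d MCS), acceptance %.3g\n",
              dim(x$cms)[2], dim(x$cms)[1], min(x$times), max(x$times),
              x$acceptance))
  invisible(x)
}
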