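#' Structural and dynamic summary of a finished run
#'
#' Computes, from a recorded trajectory, the observables used throughout the
#' surface-tension scans: the hexatic order `<|psi6|>` averaged over cells
#' and samples, the diffusion exponent `beta` and coefficient `D_eff` from
#' the single-origin MSD, and the Voronoi shape statistics of the cell
#' centers (isoperimetric quotient `q_V`, generalized edge number `n*`,
#' circularity `C_V`), pooled over the selected samples.
#'
#' @param trajectory a `cpm_trajectory` from [run_cpm()].
#' @param shape_samples indices of trajectory samples whose centers enter
#'   the shape/psi6 pools (default: every sample after the MSD origin).
#' @param fit_window,beta_gate passed to [fit_beta_deff()].
#' @param n_bins,fit_halfwidth passed to [distribution_summary()] for the
#'   pooled `n*` and `C_V` distributions.
#' @return List with `psi6_mean`, `psi6_sem` (over per-sample means),
#'   `beta`, `beta_err`, `deff`, `q_v`, `n_star`, `c_v` (pooled vectors),
#'   `fractions` (pseudo-polygon table), `f5`, `f6`, `mode_cv`,
#'   `nstar_summary`, `cv_summary`, `acceptance`.
#' @export
characterize_run <- function(trajectory, shape_samples = NULL,
                             fit_window = NULL, beta_gate = 0.05,
                             n_bins = 60, fit_halfwidth = 3) {
  nt <- dim(trajectory$cms)[1]
  if (is.null(shape_samples)) shape_samples <- seq(2L, nt)
  shape_samples <- shape_samples[shape_samples >= 1 & shape_samples <= nt]
  if (!length(shape_samples)) stop("no valid shape samples")

  psi_means <- numeric(length(shape_samples))
  qv <- cv <- vector("list", length(shape_samples))
  for (k in seq_along(shape_samples)) {
    ctr <- traj_centers(trajectory, shape_samples[k])
    psi_means[k] <- psi6(ctr, trajectory$box)$mean_abs
    sh <- voronoi_shapes(ctr, trajectory$box)
    qv[[k]] <- sh$q_v
    cv[[k]] <- sh$C_v
  }
  qv <- unlist(qv)
  cv <- unlist(cv)
  ns <- suppressWarnings(n_star(pmin(qv, 1 - 1e-12)))

  dyn <- tryCatch(fit_beta_deff(msd(trajectory), fit_window, beta_gate),
                  error = function(e) list(beta = NA_real_, beta_err = NA_real_,
                                           D_eff = NA_real_))
  fr <- pseudo_fractions(ns)
  getf <- function(k) {
    i <- match(k, fr$n)
    if (is.na(i)) 0 else fr$fraction[i]
  }
  ns_sum <- tryCatch(distribution_summary(ns, n_bins, fit_halfwidth),
                     error = function(e) NULL)
  cv_sum <- tryCatch(distribution_summary(cv, n_bins, fit_halfwidth),
                     error = function(e) NULL)
  list(psi6_mean = mean(psi_means),
       psi6_sem = if (length(psi_means) > 1)
         stats::sd(psi_means) / sqrt(length(psi_means)) else NA_real_,
       beta = dyn$beta, beta_err = dyn$beta_err, deff = dyn$D_eff,
       q_v = qv, n_star = ns, c_v = cv, fractions = fr,
       f5 = getf(5), f6 = getf(6),
       mode_cv = if (is.null(cv_sum)) NA_real_ else cv_sum$peaks[1],
       nstar_summary = ns_sum, cv_summary = cv_sum,
       acceptance = trajectory$acceptance)
}

#' Run a surface-tension scan on one lattice
#'
#' For each alpha and replicate, initializes the cells (rectangles in and
#' below the transition region, a hexagonal crystal above
#' `hex_init_above` — the crystalline start substitutes for re-using an
#' equilibrated high-tension snapshot and only affects equilibration time),
#' runs the dynamics, summarizes it with [characterize_run()], and
#' aggregates across replicates with [aggregate_scan()].
#'
#' @param lattice a `poly_lattice`.
#' @param alphas increasing vector of surface tensions.
#' @param n_runs replicates per alpha.
#' @param base_seed integer; replicate seeds are derived deterministically.
#' @param t_w,t_s,sample_every protocol per run (sweeps).
#' @param lam,A0,kT Hamiltonian parameters.
#' @param hex_init_above alphas strictly above this start from
#'   [init_hex_cells()]; others from [init_rectangles()].
#' @param cell_w,cell_h rectangle dimensions of the disordered start.
#' @param progress print one line per finished run.
#' @return List with `runs` (one row per run: alpha, run, psi6, beta, deff,
#'   f5, f6, mode_cv, nstar_peak, nstar_min) and `scan`
#'   (the aggregated table).
#' @export
run_alpha_scan <- function(lattice, alphas, n_runs = 1, base_seed = 1L,
                           t_w = 2000L, t_s = 4000L, sample_every = 50L,
                           lam = 1, A0 = 40, kT = 1, hex_init_above = 2.2,
                           cell_w = 5, cell_h = 8, progress = FALSE) {
  rows <- list()
  for (ai in seq_along(alphas)) {
    for (r in seq_len(n_runs)) {
      seed <- (base_seed * 1000L + ai * 100L + r) %% .Machine$integer.max
      p <- sim_params(alpha = alphas[ai], lam = lam, A0 = A0, kT = kT,
                      seed = seed, t_w = t_w, t_s = t_s,
                      sample_every = sample_every)
      field <- if (alphas[ai] > hex_init_above) init_hex_cells(lattice, A0)
               else init_rectangles(lattice, cell_w, cell_h)
      traj <- run_cpm(lattice, field, p)
      ch <- characterize_run(traj)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = alphas[ai], run = r,
        psi6 = ch$psi6_mean, beta = ch$beta, deff = ch$deff,
        f5 = ch$f5, f6 = ch$f6, mode_cv = ch$mode_cv,
        nstar_peak = if (is.null(ch$nstar_summary)) NA_real_
                     else ch$nstar_summary$peaks[1],
        nstar_min = if (is.null(ch$nstar_summary)) NA_real_
                    else ch$nstar_summary$minimum)
      if (progress)
        message(sprintf("alpha = %.3g run %d: psi6 = %.3f, beta = %.3g, D = %.3g",
                        alphas[ai], r, ch$psi6_mean, ch$beta, ch$deff))
    }
  }
  runs <- do.call(rbind, rows)
  list(runs = runs, scan = aggregate_scan(runs))
}

#' Synthetic scan table with a planted transition
#'
#' Builds a scan table whose `deff` follows a decreasing logistic in
#' `log10`, centered at `alpha0` with width `width`; whose `log(f6/f5)`
#' crosses zero at `alpha0`; and whose `mode_cv` crosses the
#' regular-pentagon circularity at `alpha0`. Used as a known-truth input for
#' the transition estimators and as a bundled fixture generator.
#'
#' @param alphas scan grid.
#' @param alpha0 planted transition location.
#' @param width logistic width of the `deff` drop.
#' @param log_d_hi,log_d_lo `log10 D_eff` plateaus below/above the
#'   transition.
#' @param ratio_slope slope of `log(f6/f5)` in alpha.
#' @param mode_slope slope of `mode_cv` in alpha.
#' @param noise_sd Gaussian noise added to `log10 deff` (0 = exact).
#' @return Data frame with columns `alpha`, `deff`, `f5`, `f6`, `mode_cv`.
#' @export
synthetic_scan <- function(alphas = seq(1.2, 3.0, by = 0.1), alpha0 = 2.1,
                           width = 0.1, log_d_hi = -1, log_d_lo = -4,
                           ratio_slope = 4, mode_slope = 0.02, noise_sd = 0) {
  logd <- log_d_hi + (log_d_lo - log_d_hi) / (1 + exp(-(alphas - alpha0) / width))
  if (noise_sd > 0) logd <- logd + stats::rnorm(length(alphas), sd = noise_sd)
  logratio <- ratio_slope * (alphas - alpha0)
  tot <- 0.8
  f5 <- tot / (1 + exp(logratio))
  f6 <- tot - f5
  data.frame(alpha = alphas, deff = 10^logd, f5 = f5, f6 = f6,
             mode_cv = c_pentagon() + mode_slope * (alphas - alpha0))
}
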