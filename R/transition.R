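#' Aggregate per-run summaries into a surface-tension scan table
#'
#' Groups run-level metric rows by the control parameter `alpha` and returns
#' per-alpha means with standard errors across independent runs. Columns
#' listed in `id_cols` must be constant within each alpha group (they
#' identify the lattice/protocol; mixing configurations in one group is an
#' error). Single-run groups get `NA` standard errors.
#'
#' @param runs data frame with a numeric `alpha` column and one row per run;
#'   all other numeric columns are aggregated.
#' @param id_cols character vector of configuration-identifier columns.
#' @return Data frame sorted by increasing `alpha`, with `n_runs` and, for
#'   every metric `m`, columns `m` (mean over runs with the metric present)
#'   and `m_sem`.
#' @export
aggregate_scan <- function(runs, id_cols = intersect("config", names(runs))) {
  if (!"alpha" %in% names(runs)) stop("runs must have an 'alpha' column")
  if (length(unique(runs$alpha)) < 4) stop("need at least 4 alpha values")
  for (ic in id_cols) {
    bad <- tapply(runs[[ic]], runs$alpha, function(x) length(unique(x)) > 1)
    if (any(bad)) stop("inconsistent '", ic, "' within an alpha group")
  }
  metrics <- setdiff(names(runs)[vapply(runs, is.numeric, logical(1))],
                     c("alpha", "run"))
  alphas <- sort(unique(runs$alpha))
  out <- data.frame(alpha = alphas,
                    n_runs = as.integer(table(factor(runs$alpha, levels = alphas))))
  for (m in metrics) {
    vals <- split(runs[[m]], factor(runs$alpha, levels = alphas))
    out[[m]] <- vapply(vals, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out[[paste0(m, "_sem")]] <- vapply(vals, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Localize the fluid-solid transition from the diffusion coefficient
#'
#' Fits a polynomial (default degree 4) to `log10(D_eff)` as a function of
#' alpha and reports two markers: `alpha_inflection`, the interior zero of
#' the second derivative nearest the point of steepest descent (posited to
#' sit mid-coexistence and hence to overestimate the transition), and
#' `alpha_dropoff`, the interior point of maximally negative curvature,
#' where the diffusion coefficient starts its rapid drop (posited to sit at
#' the end of the disordered branch, so `alpha_dropoff <= alpha_inflection`).
#' Alphas whose `D_eff` is absent (diffusive gate failed) are excluded from
#' the fit.
#'
#' @param scan data frame with columns `alpha` and `deff` (e.g. from
#'   [aggregate_scan()]).
#' @param degree polynomial degree (3-6), or `"auto"` to pick, among the
#'   degrees that yield an interior curvature minimum, the one with the
#'   lowest BIC.
#' @param grid_step resolution of the dense alpha grid used to locate the
#'   markers.
#' @return List with `alpha_inflection`, `alpha_dropoff`, `deff_dropoff`
#'   (fitted `D_eff` at the drop-off), `degree`, `residuals`.
#' @export
locate_transition_deff <- function(scan, degree = 4, grid_step = 1e-4) {
  if (!all(c("alpha", "deff") %in% names(scan)))
    stop("scan must have 'alpha' and 'deff' columns")
  if (identical(degree, "auto")) {
    ok <- is.finite(scan$deff) & scan$deff > 0
    cand <- 3:6
    cand <- cand[cand + 2 <= sum(ok)]
    bic <- vapply(cand, function(d) {
      a <- scan$alpha[ok]; y <- log10(scan$deff[ok])
      stats::BIC(stats::lm(y ~ stats::poly(a, d, raw = TRUE)))
    }, numeric(1))
    errs <- character(0)
    for (d in cand[order(bic)]) {
      res <- tryCatch(locate_transition_deff(scan, degree = d, grid_step = grid_step),
                      error = function(e) conditionMessage(e))
      if (!is.character(res)) return(res)
      errs <- c(errs, res)
    }
    stop("no transition in range for any degree (", errs[1], ")")
  }
  if (!degree %in% 3:6) stop("degree must be between 3 and 6")
  ok <- is.finite(scan$deff) & scan$deff > 0
  if (sum(ok) < degree + 1 || sum(ok) < 5)
    stop("need at least 5 alpha values with a finite positive D_eff")
  a <- scan$alpha[ok]
  y <- log10(scan$deff[ok])
  fit <- stats::lm(y ~ stats::poly(a, degree, raw = TRUE))
  cf <- as.numeric(stats::coef(fit))
  grid <- seq(min(a), max(a), by = grid_step)
  pow <- seq_len(degree)
  d1 <- rowSums(sapply(pow, function(k) k * cf[k + 1] * grid^(k - 1)))
  d2 <- rowSums(sapply(pow[-1], function(k) k * (k - 1) * cf[k + 1] * grid^(k - 2)))

  curv_scale <- diff(range(y)) / diff(range(a))^2
  if (max(abs(d2)) <= 1e-6 * max(curv_scale, 1e-12))
    stop("no transition in range: fitted curve has no curvature")

  interior <- seq(2L, length(grid) - 1L)
  imin <- interior[which.min(d2[interior])]
  if (imin <= 2L || imin >= length(grid) - 1L)
    stop("no transition in range: curvature minimum sits on the scan boundary")
  alpha_dropoff <- grid[imin]

  sgn <- sign(d2)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flips))
    stop("no transition in range: second derivative does not change sign")
  roots <- (grid[flips] + grid[flips + 1]) / 2
  steepest <- grid[interior[which.min(d1[interior])]]
  alpha_inflection <- roots[which.min(abs(roots - steepest))]

  yhat <- sum(cf * alpha_dropoff^(0:degree))
  list(alpha_inflection = alpha_inflection, alpha_dropoff = alpha_dropoff,
       deff_dropoff = 10^yhat, degree = degree,
       residuals = unname(stats::residuals(fit)))
}

#' Crossover of the pseudo-hexagon and pseudo-pentagon fractions
#'
#' The alpha at which `f6 / f5 = 1`: to crystallize, the tissue must have a
#' majority of pseudo-hexagons, and this crossover tracks the transition.
#' The crossing of `log(f6/f5)` is linearly interpolated in alpha between
#' the bracketing scan points; an exact hit at a grid point returns that
#' alpha.
#'
#' @param scan data frame with columns `alpha`, `f5`, `f6`.
#' @return The crossover alpha (scalar).
#' @export
crossover_alpha <- function(scan) {
  if (!all(c("alpha", "f5", "f6") %in% names(scan)))
    stop("scan must have 'alpha', 'f5', 'f6' columns")
  ok <- is.finite(scan$f5) & is.finite(scan$f6) & scan$f5 > 0 & scan$f6 > 0
  s <- scan[ok, ]
  s <- s[order(s$alpha), ]
  r <- log(s$f6 / s$f5)
  hit <- which(r == 0)
  if (length(hit)) return(s$alpha[hit[1]])
  flip <- which(r[-1] * r[-length(r)] < 0)
  if (!length(flip)) stop("f6/f5 never crosses 1 in the scanned range")
  i <- flip[1]
  s$alpha[i] + (0 - r[i]) * (s$alpha[i + 1] - s$alpha[i]) / (r[i + 1] - r[i])
}

#' Transition alpha from the mode of the circularity distribution
#'
#' The alpha at which the mode of the Voronoi-circularity distribution
#' equals the regular-pentagon circularity `C(5)` — an excellent transition
#' estimator: below the transition the most common cell is rounder than a
#' pentagon, above it the mode moves toward the hexagon value. Linear
#' interpolation of `mode(C_V) - C(5)` to its zero.
#'
#' @param scan data frame with columns `alpha` and `mode_cv`.
#' @return The crossing alpha (scalar).
#' @export
mode_c5_indicator <- function(scan) {
  if (!all(c("alpha", "mode_cv") %in% names(scan)))
    stop("scan must have 'alpha' and 'mode_cv' columns")
  s <- scan[is.finite(scan$mode_cv), ]
  s <- s[order(s$alpha), ]
  d <- s$mode_cv - c_pentagon()
  hit <- which(d == 0)
  if (length(hit)) return(s$alpha[hit[1]])
  flip <- which(d[-1] * d[-length(d)] < 0)
  if (!length(flip)) stop("mode(C_V) never crosses C(5) in the scanned range")
  i <- flip[1]
  s$alpha[i] + (0 - d[i]) * (s$alpha[i + 1] - s$alpha[i]) / (d[i + 1] - d[i])
}
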