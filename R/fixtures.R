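#' Deterministic small test inputs
#'
#' Writes a set of small, plain-text fixtures, regenerated bit-identically
#' from the seed: a 16 x 16 square lattice, a 12 x 12 hexagonal lattice, a
#' 256-site fluid-derived Voronoi lattice (all as JSON lattice files), a
#' synthetic diffusive center-of-mass trajectory (CSV), and a synthetic
#' sigmoidal scan table with a planted transition (CSV).
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed for every stochastic ingredient.
#' @return Named character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(square = file.path(dir, "lattice_square16.json"),
             hex = file.path(dir, "lattice_hex12.json"),
             fluid = file.path(dir, "lattice_fluid256.json"),
             traj = file.path(dir, "trajectory_diffusive.csv"),
             scan = file.path(dir, "scan_sigmoid.csv"))

  save_lattice(build_square_lattice(16, 16, 1), paths[["square"]])
  save_lattice(build_hexagonal_lattice(12, 12, 1), paths[["hex"]])
  save_lattice(fluid_voronoi_lattice(256, t_w = 200L, seed = seed),
               paths[["fluid"]])

  set.seed(seed + 1L)
  n_cells <- 64L
  n_t <- 101L
  s <- 0.3
  dx <- matrix(stats::rnorm(n_t * n_cells, sd = s), n_t, n_cells)
  dy <- matrix(stats::rnorm(n_t * n_cells, sd = s), n_t, n_cells)
  dx[1, ] <- 0; dy[1, ] <- 0
  x <- apply(dx, 2, cumsum)
  y <- apply(dy, 2, cumsum)
  tab <- data.frame(t_sweep = rep(0:(n_t - 1L), times = n_cells),
                    cell_id = rep(seq_len(n_cells), each = n_t),
                    x_unwrapped = as.numeric(x), y_unwrapped = as.numeric(y))
  utils::write.csv(tab, paths[["traj"]], row.names = FALSE)

  utils::write.csv(synthetic_scan(), paths[["scan"]], row.names = FALSE)
  paths
}

#' Read a center-of-mass trajectory table back into trajectory form
#'
#' Inverse of the CSV layout written by the command-line tools and
#' [make_fixtures()] (columns `t_sweep`, `cell_id`, `x_unwrapped`,
#' `y_unwrapped`).
#'
#' @param path CSV file path.
#' @param box periodic box (needed only for wrapped-center queries).
#' @return A list mimicking a `cpm_trajectory` (`times`, `cms`, `box`).
#' @export
read_cms_table <- function(path, box = c(Inf, Inf)) {
  tab <- utils::read.csv(path)
  need <- c("t_sweep", "cell_id", "x_unwrapped", "y_unwrapped")
  if (!all(need %in% names(tab)))
    stop("trajectory table must have columns ", paste(need, collapse = ", "))
  times <- sort(unique(tab$t_sweep))
  cells <- sort(unique(tab$cell_id))
  cms <- array(NA_real_, dim = c(length(times), length(cells), 2))
  ti <- match(tab$t_sweep, times)
  ci <- match(tab$cell_id, cells)
  cms[cbind(ti, ci, 1L)] <- tab$x_unwrapped
  cms[cbind(ti, ci, 2L)] <- tab$y_unwrapped
  structure(list(times = times, cms = cms, box = box), class = "cpm_trajectory")
}

# CSV form of a trajectory (used by the CLI and fixtures)
cms_table <- function(trajectory) {
  nt <- dim(trajectory$cms)[1]
  nc <- dim(trajectory$cms)[2]
  data.frame(t_sweep = rep(trajectory$times, times = nc),
             cell_id = rep(seq_len(nc), each = nt),
             x_unwrapped = as.numeric(trajectory$cms[, , 1]),
             y_unwrapped = as.numeric(trajectory$cms[, , 2]))
}
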