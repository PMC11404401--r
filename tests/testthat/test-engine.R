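p_std <- function(...) sim_params(..., seed = 1L)

test_that("total energy matches hand-computed configurations", {
  lat <- build_square_lattice(4, 4, 1)
  one <- spin_field(lat, rep(1, 16))
  e <- total_energy(lat, one, p_std(alpha = 1, lam = 1, A0 = 16))
  expect_equal(e$total, 0)
  expect_equal(e$surface + e$area, e$total)

  e2 <- total_energy(lat, one, p_std(alpha = 1, lam = 1, A0 = 12))
  expect_equal(e2$surface, 0)
  expect_equal(e2$area, 16)

  # two cells of two columns each; 12 unlike Moore pairs per interface
  cols <- spin_field(lat, rep(c(1, 1, 2, 2), 4))
  e3 <- total_energy(lat, cols, p_std(alpha = 1, lam = 1, A0 = 8))
  expect_equal(e3$surface, 24)
})

test_that("local energy difference equals the brute-force total difference", {
  set.seed(77)
  lat <- build_square_lattice(6, 6, 1)
  latv <- fixture_small_fluid_lattice()
  for (cfg in list(list(lat = lat, p = p_std(alpha = 1.3, lam = 0.7, A0 = 6)),
                   list(lat = latv, p = p_std(alpha = 1.1, lam = 1, A0 = 40)))) {
    f <- init_rectangles(cfg$lat, 3, 2)
    maxerr <- 0
    for (k in 1:1500) {
      i <- sample(cfg$lat$n_sites, 1)
      ns <- sample(setdiff(seq_len(f$n_cells), f$spin[i]), 1)
      dE <- delta_energy(cfg$lat, f, cfg$p, i, ns)
      e0 <- total_energy(cfg$lat, f, cfg$p)$total
      f2 <- f
      f2$spin[i] <- ns
      f2$cell_area <- polypotts:::recompute_areas(cfg$lat, f2)
      e1 <- total_energy(cfg$lat, f2, cfg$p)$total
      maxerr <- max(maxerr, abs(dE - (e1 - e0)))
      if (stats::runif(1) < 0.5) f <- f2
    }
    expect_lt(maxerr, 1e-10)
  }
  # same-spin proposals are the caller's error
  f <- init_rectangles(lat, 3, 2)
  expect_error(delta_energy(lat, f, p_std(alpha = 1), 1, f$spin[1]), "same-spin")
})

test_that("area-term change follows the quadratic identity", {
  lat <- build_square_lattice(5, 5, 1)
  f <- init_rectangles(lat, 2, 5)
  p <- p_std(alpha = 1e-14, lam = 2.5, A0 = 9)
  i <- which(f$spin == 1)[1]
  ai <- lat$area[i]
  a1 <- f$cell_area[1]; a2 <- f$cell_area[2]
  want <- 2.5 * ((a1 - ai - 9)^2 + (a2 + ai - 9)^2 - (a1 - 9)^2 - (a2 - 9)^2)
  expect_equal(delta_energy(lat, f, p, i, 2), want, tolerance = 1e-9)
})

test_that("Metropolis acceptance matches the Boltzmann factor", {
  lat <- build_square_lattice(4, 4, 1)
  cols <- spin_field(lat, rep(c(1, 1, 2, 2), 4))
  # every cross-cell flip in this state costs exactly 2 * alpha
  pa <- p_std(alpha = log(2) / 2, lam = 1e-14, A0 = 8, kT = 1)
  set.seed(5)
  n_acc <- 0L; n_prop <- 0L
  for (k in 1:30000) {
    r <- cpm_attempt(lat, cols, pa, commit = FALSE)
    if (!r$same_spin) {
      expect_equal(r$delta_e, log(2), tolerance = 1e-9)
      n_prop <- n_prop + 1L
      n_acc <- n_acc + r$accepted
    }
  }
  phat <- n_acc / n_prop
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n_prop))

  # zero-temperature limit: uphill moves never accepted
  pz <- p_std(alpha = log(2) / 2, lam = 1e-14, A0 = 8, kT = 1e-12)
  set.seed(6)
  acc0 <- 0L
  for (k in 1:5000) {
    r <- cpm_attempt(lat, cols, pz, commit = FALSE)
    if (!r$same_spin) acc0 <- acc0 + r$accepted
  }
  expect_equal(acc0, 0L)
})

test_that("sweeps are deterministic under a fixed seed and respect no-op picks", {
  lat <- build_square_lattice(5, 5, 1)
  one <- spin_field(lat, rep(1, 25))
  p <- p_std(alpha = 2, lam = 1, A0 = 25)
  set.seed(1)
  r <- cpm_sweep(lat, one, p, 10)   # frozen single cell: all picks same-spin
  expect_equal(sum(r$accepted), 0L)
  expect_identical(r$field$spin, one$spin)

  f <- init_rectangles(lat, 2, 2)
  set.seed(42)
  r1 <- cpm_sweep(lat, f, p, 20)
  set.seed(42)
  r2 <- cpm_sweep(lat, f, p, 20)
  expect_identical(r1$field$spin, r2$field$spin)
  expect_identical(r1$accepted, r2$accepted)
  expect_length(r1$accepted, 20)

  # vanishing couplings: every unlike-spin proposal is accepted
  p0 <- p_std(alpha = 1e-14, lam = 1e-14, A0 = 8)
  set.seed(7)
  moved <- 0L
  f0 <- init_rectangles(lat, 2, 2)
  for (k in 1:2000) {
    r <- cpm_attempt(lat, f0, p0, commit = FALSE)
    if (!r$same_spin) {
      moved <- moved + 1L
      expect_true(r$accepted)
    }
  }
  expect_gt(moved, 0L)
})

test_that("rectangular initialization tiles the box confluently", {
  lat <- build_square_lattice(200, 200, 1)
  f <- init_rectangles(lat, 5, 8)
  expect_equal(f$n_cells, 1000)
  expect_true(all(f$cell_area == 40))
  expect_equal(sum(f$cell_area), prod(lat$box))

  lat2 <- build_square_lattice(10, 8, 1)
  f2 <- init_rectangles(lat2, 5, 8)
  expect_equal(f2$n_cells, 2)
  expect_true(all(f2$cell_area == 40))

  latv <- fixture_small_fluid_lattice()
  fv <- init_rectangles(latv, 5, 8)
  expect_equal(sum(fv$cell_area), prod(latv$box), tolerance = 1e-10)
})

test_that("hexagonal-crystal initialization produces perfect hexatic order", {
  # hexagonal site lattice grouped 36:1 into cells of area 40: exact tiling
  lat <- build_hexagonal_lattice(36, 36, 40 / 36)
  f <- init_hex_cells(lat, 40)
  expect_equal(f$n_cells, 36)
  expect_equal(sum(f$cell_area), prod(lat$box), tolerance = 1e-8)
  ctr <- polypotts:::wrap_box(cell_cms(lat, f), lat$box)
  a <- psi6(ctr, lat$box)$abs_psi6
  # nearest-center assignment resolves equidistant boundary sites
  # asymmetrically, so centers of mass sit within a fraction of a site of the
  # exact triangular grid; order stays essentially perfect
  expect_gte(min(a), 0.99)
  expect_gte(mean(a), 0.995)
  # honeycomb symmetry: every cell has 6 neighbor cells
  nb_cells <- lapply(seq_len(lat$n_sites), function(i)
    unique(f$spin[lat$neighbors[[i]]]))
  for (c in seq_len(36)) {
    neigh <- unique(unlist(nb_cells[f$spin == c]))
    expect_length(setdiff(neigh, c), 6)
  }
  expect_error(init_hex_cells(build_square_lattice(9, 9, 1), 40), "tileable")
})

test_that("fragmentation report counts connected components per cell", {
  lat <- build_square_lattice(6, 6, 1)
  f <- init_rectangles(lat, 3, 3)
  expect_true(all(fragmentation_report(lat, f) == 1))
  # split cell 1 into two opposite blocks separated by cell 2
  spin <- f$spin
  spin[] <- 2L
  spin[c(1, 2, 7, 8)] <- 1L      # block at one corner
  spin[c(21, 22, 27, 28)] <- 1L  # detached block (not even corner-touching)
  f2 <- spin_field(lat, spin)
  expect_equal(unname(fragmentation_report(lat, f2)[1]), 2L)
})

test_that("trajectories are reproducible and keep exact confluency", {
  lat <- fixture_small_fluid_lattice()
  f <- init_rectangles(lat, 5, 8)
  p <- sim_params(alpha = 1.2, lam = 1, A0 = 40, seed = 8, t_w = 50, t_s = 200,
                  sample_every = 25)
  tr1 <- run_cpm(lat, f, p)
  tr2 <- run_cpm(lat, f, p)
  expect_identical(tr1$cms, tr2$cms)
  expect_identical(tr1$field$spin, tr2$field$spin)
  expect_equal(dim(tr1$cms)[1], 9)  # origin + 8 samples

  # incremental bookkeeping matches recomputation after many accepted moves
  expect_lt(max(abs(tr1$field$cell_area -
                    polypotts:::recompute_areas(lat, tr1$field))), 1e-8)
  expect_lt(abs(sum(tr1$field$cell_area) - prod(lat$box)), 1e-8 * prod(lat$box))

  # no-dynamics run returns the single initial sample
  tr0 <- run_cpm(lat, f, sim_params(alpha = 1.2, A0 = 40, seed = 8))
  expect_equal(dim(tr0$cms)[1], 1)
  expect_true(all(fragmentation_report(lat, tr0$field) >= 1))
})

test_that("a zero-temperature quench at high surface tension relaxes monotonically", {
  lat <- build_square_lattice(20, 20, 1)
  f <- init_rectangles(lat, 4, 5)
  # melt first so the quench starts from a disordered state
  set.seed(3)
  f <- cpm_sweep(lat, f, sim_params(alpha = 0.8, lam = 1, A0 = 20, seed = 3),
                 200)$field
  p <- sim_params(alpha = 3, lam = 1, A0 = 20, kT = 1e-12, seed = 3)
  e <- total_energy(lat, f, p)$total
  energies <- e
  for (s in 1:30) {
    f <- cpm_sweep(lat, f, p, 1)$field
    energies <- c(energies, total_energy(lat, f, p)$total)
  }
  expect_true(all(diff(energies) <= 1e-9))
  expect_lt(energies[length(energies)], energies[1])
})

test_that("uniform and edge-weighted modes agree on the hexagonal lattice", {
  latu <- build_hexagonal_lattice(6, 6, 1, weight_mode = "uniform")
  late <- build_hexagonal_lattice(6, 6, 1, weight_mode = "edge-weighted")
  f <- init_rectangles(latu, 1.5, 2)
  p <- p_std(alpha = 1.7, lam = 1, A0 = 3)
  for (k in 1:50) {
    i <- sample(latu$n_sites, 1)
    ns <- sample(setdiff(seq_len(f$n_cells), f$spin[i]), 1)
    expect_equal(delta_energy(latu, f, p, i, ns),
                 delta_energy(late, f, p, i, ns), tolerance = 1e-10)
  }
})
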