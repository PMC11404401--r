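---
title: "Cellular Potts dynamics on polygonal lattices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular Potts dynamics on polygonal lattices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`polypotts` simulates confluent monolayers of monodisperse cells with the
cellular Potts (Glazier–Graner–Hogeweg) model, generalized so that the same
dynamics runs on any periodic polygonal lattice. A configuration assigns to
every lattice site $i$ a cell index $\sigma(i)$; every site belongs to
exactly one cell (confluency), and a cell is the union of its member
polygons. The energy is

$$H = \alpha \sum_{(i,j)} w_{ij}\,\bigl(1 - \delta_{\sigma(i)\sigma(j)}\bigr)
    \;+\; \lambda \sum_{\sigma} (a_\sigma - A_0)^2 ,$$

where the first sum runs over **distinct** neighbor pairs (each unordered
pair counted once), $\alpha$ is the surface tension between unlike cells,
$a_\sigma$ is the instantaneous cell area, $A_0$ the target area and
$\lambda$ the area-spring strength. Two sites are neighbors when their
polygons share at least one vertex; on the square lattice this is the Moore
8-neighborhood, on the hexagonal lattice the 6-neighborhood, and on
irregular lattices the neighbor count varies per site. The weight
$w_{ij} = l_{ij}/\bar l$ makes the surface energy proportional to the
shared contact length $l_{ij}$, with $\bar l$ the mean length of all
distinct positive-length edges of the lattice. On regular lattices the
conventional choice $w_{ij} = 1$ is the default (`weight_mode =
"uniform"`), under which the Hamiltonian reduces to the classic form.

Dynamics is Metropolis Monte Carlo: pick a site uniformly, pick an invading
site uniformly from its full neighbor list, and — when the spins differ —
copy the invader's spin with probability $\min\{1, e^{-\Delta E/k_BT}\}$.
Same-spin picks consume an attempt; $N_s$ attempts define one Monte-Carlo
sweep (MCS), the model's time unit. $k_BT$ scales the rate of membrane
fluctuations and is 1 by default.

### Conventions the energy scale depends on

* Each unordered pair enters the surface sum once. A double-counting
  convention would simply rescale $\alpha$ by two; fixing the convention
  keeps $\alpha$ values comparable across lattices and with the vertex- and
  Voronoi-model literature this model is compared against.
* Vertex-only contacts (polygons sharing a single point: the diagonals of a
  square grid, or degenerate co-circular Voronoi configurations) are kept
  in the adjacency. They allow copy attempts but have $l_{ij} = 0$, hence
  $w_{ij} = 0$ in edge-weighted mode: no surface energy flows through a
  point contact. $\bar l$ averages positive-length edges only, so these
  contacts do not dilute the weight normalization.
* The invading neighbor is drawn uniformly from the neighbor list, not
  proportionally to contact length; this matches the regular-lattice
  algorithm the model generalizes. (A contact-length-weighted proposal
  would be a different, also legitimate, kinetic rule; the equilibrium
  ensemble these simulations probe is set by $H$ either way.)

## Lattices

`build_square_lattice()` and `build_hexagonal_lattice()` construct the
regular substrates; the hexagonal builder reuses the periodic Voronoi
machinery on a triangular generator grid, so regular and irregular
lattices are guaranteed to be structurally consistent. `n_rows` must be
even for the hexagonal tiling to close periodically.

`build_voronoi_lattice()` computes the periodic Voronoi tessellation of an
arbitrary generator set by per-cell half-plane clipping: each cell starts
from a rectangle larger than the box and is clipped by the bisector of
every other generator image in order of increasing distance, stopping once
the next candidate is farther than twice the farthest remaining vertex
(the security-radius bound, which makes the construction exact, not
heuristic). The generator's own periodic images participate: if one of
them contributes an edge, the cell wraps around the box and the input is
rejected as too sparse for the box. Numerical choices:

* vertices closer than `tol` (default $10^{-9}$, absolute) are merged, and
  sub-tolerance edges are demoted to vertex-only contacts;
* a bisector through a vertex (grazing contact) does not modify the
  polygon — the shared-vertex pass recovers the contact afterwards by
  hashing all cell vertices on a `tol` grid;
* contact lengths of a pair that touches across several periodic images
  are summed into one adjacency entry, and the two independent per-cell
  length estimates of each edge are averaged (they agree to rounding).

Every constructor runs `validate_lattice()`: site areas must sum to the
box area ($10^{-8}$ relative), the adjacency must be symmetric with
consistent lengths, no site may neighbor itself, and the mean edge weight
over distinct positive-length edges must be 1 in edge-weighted mode.

### The disordered lattice

Uniformly random generators produce many tiny and a few huge Voronoi
cells. Instead, the disordered substrate derives from a simulated fluid:
`generate_fluid_centers()` runs a square-lattice simulation at
$\alpha = 0.8$, $\lambda = 1$, $k_BT = 1$, $A_0 = 40$ (a fluid state of
uniformly sized cells) and returns the cells' centers of mass;
`fluid_voronoi_lattice()` tessellates them after rescaling to unit mean
site area. The default target box preserves the generator's aspect ratio —
an anisotropic rescale would imprint a global stretch on an otherwise
isotropic lattice. Structure is checked with `isotropy_check()`: the
points are rastered to a 512² image, Fourier transformed, and the
anisotropy score is the coefficient of variation of $\log(1+|F|^2)$ over
36 angular bins of the first structure-factor ring
($[0.7, 1.3] \times 2\pi/u$, $u = \sqrt{\text{box area}/n}$). The log
compression is the scale on which transform images are conventionally
inspected; without it, speckle noise in a sharp ring dominates the
statistic and masks genuine anisotropy. A triangular crystal scores two
orders of magnitude above a uniform-random set; fluid-derived centers
score within a factor ~1.5 of it.

## Initial conditions

`init_rectangles()` tiles the box with (nominally) 5 × 8 rectangles — the
standard disordered start. `init_hex_cells()` assigns sites to the nearest
center of a triangular grid of hexagons with area $A_0$, giving a
crystalline start for high-surface-tension runs where melting a rectangle
tiling would take prohibitively long; it replaces the alternative of
continuing from an equilibrated high-tension snapshot and only affects the
equilibration time, which is configurable. The box must be tileable within
`max_distortion` (3% by default) of regular hexagons of area $A_0$.
Because sites equidistant to two hexagon centers are assigned
deterministically to one of them, the initial cell centers sit within a
fraction of a site of the exact triangular grid: the initial
$\langle|\psi_6|\rangle$ exceeds 0.99 rather than being exactly 1.

## Observables

**Centers of mass.** `cell_cms()` computes area-weighted centroids with
minimum-image displacements relative to a per-cell reference (the previous
center along a trajectory), which unwraps trajectories continuously across
the periodic boundary.

**MSD, $\beta$, $D_\mathrm{eff}$.** `msd()` uses a single time origin at
the end of equilibration, $\langle r^2(t)\rangle = \langle(\mathbf r(t +
t_w) - \mathbf r(t_w))^2\rangle$, averaged over cells. `fit_beta_deff()`
fits $\beta$ as the log–log slope over the last decade of lag times (the
long-time regime) and reports $D_\mathrm{eff}$ as the window mean of
$\langle r^2\rangle/(4t)$ — exact for ideal diffusion and more robust than
an intercept fit on short windows — only when $|\beta - 1| \le
\max(0.05, \mathrm{SE}(\beta))$. Multi-origin averaging exists as an
option but is off by default, since the single-origin definition is what
the scan results use.

**Hexatic order.** `psi6()` uses the six nearest centers by minimum-image
distance, $\psi_6(k) = \tfrac16\sum_j e^{6i\theta(j,k)}$, with distance
ties broken by (distance, cell id) so that degenerate geometries (e.g.
square grids of centers) give a deterministic, reproducible value.
$\langle|\psi_6|\rangle$ averages $|\psi_6|$ over cells and samples. Note
that this is an instantaneous-center quantity: thermal jitter of the
centers of mass depresses it noticeably below the value one would obtain
from time-averaged cell positions, especially in the solid phase at
$k_BT = 1$, where it saturates well below 1 even in a defect-free crystal.

## Shape metrics

Lattice-based cell borders are jagged: their raw perimeter is metrically
inflated, so shapes are measured on the periodic Voronoi polygons of the
cell centers (`voronoi_shapes()`), the same construction the vertex and
Voronoi models use.

* Isoperimetric quotient $q = \sqrt{4\pi A}/P$ — 1 for a disk; the
  classical $4\pi A/P^2$ is $q^2$ in this convention.
* Regular-polygon reference $q_\mathrm{reg}(n) = \sqrt{2\pi n
  \sin(2\pi/n)}/(2n\sin(\pi/n))$, evaluated for real $n$;
  $q_\mathrm{reg}(5) = 0.930$, $q_\mathrm{reg}(6) = 0.952$ to 3 d.p. Its
  numerical inverse `n_star()` defines the generalized edge number; cells
  with $n - 0.5 < n^\ast \le n + 0.5$ are pseudo-$n$-gons
  (`pseudo_fractions()`).
* Circularity $C = A^2 / (2\pi\,\mathrm{tr}\bar I)$ with $\bar I$ the
  centroidal second-moment-of-area tensor (a Hu moment invariant),
  computed from the closed-form shoelace expressions; $C = 1$ for a disk,
  $3/\pi$ for a square. The regular-polygon closed form is
  $C_\mathrm{reg}(n) = 3n\sin(2\pi/n) / \bigl(2\pi(2 + \cos(2\pi/n))\bigr)$,
  inverted by `n_circ()`; `c_pentagon()` exposes $C(5)$, the reference
  value of the transition indicator. $C$ is perimeter-free, which makes it
  robust to the border-definition issues that affect $q$.

`distribution_summary()` turns pooled per-cell values into a
density-normalized histogram (60 bins by default) with Poisson bin errors;
peak positions are refined by a quadratic fit over ±3 bins, and a
distribution is called bimodal when a secondary local maximum exceeds the
valley between the candidate modes by more than twice its bin standard
error (a persistence criterion, so that shot noise on a shoulder does not
masquerade as a mode).

## Localizing the order–disorder transition

Scans over the surface tension $\alpha$ (`run_alpha_scan()`, aggregated by
`aggregate_scan()`) are summarized per $\alpha$ by
$\langle|\psi_6|\rangle$, $\beta$, $D_\mathrm{eff}$ (absent where the
diffusive gate fails), pseudo-polygon fractions, and the circularity mode.
Three estimators localize the fluid–solid transition:

1. `locate_transition_deff()` fits a polynomial to $\log_{10}
   D_\mathrm{eff}(\alpha)$ and reports the interior curvature minimum
   (`alpha_dropoff`, the onset of the rapid drop, posited to sit at the
   end of the disordered branch) and the inflection nearest the steepest
   descent (`alpha_inflection`, posited to sit mid-coexistence and hence
   to overestimate the transition). The default degree is 4; `"auto"`
   selects, among degrees 3–6 that produce an interior curvature minimum,
   the BIC-best fit. Both markers are read off a dense grid
   ($\Delta\alpha = 10^{-4}$); a fit whose curvature never changes sign,
   or whose minimum sits on the scan boundary, raises a "no transition in
   range" error rather than returning a boundary artifact.
2. `crossover_alpha()` interpolates $\log(f_6/f_5)$ linearly in $\alpha$
   to its zero — crystallization requires a majority of pseudo-hexagons.
3. `mode_c5_indicator()` interpolates $\mathrm{mode}(C_V) - C(5)$ to its
   zero.

`synthetic_scan()` plants all three signals at a known $\alpha_0$
(logistic $\log_{10}D_\mathrm{eff}$, logistic $f_6/f_5$, linear
circularity mode) and is the generator behind the estimator tests and the
bundled scan fixture. Two properties of this construction are worth
noting: the curvature minimum of a logistic drop genuinely precedes its
midpoint (by $1.317\,w$ for width $w$), so `alpha_dropoff` is expected
below $\alpha_0$; and a polynomial fitted to a sigmoid on a window
centered at $\alpha_0$ has a vanishing quartic term by symmetry, which is
why the estimator is exercised on windows that end shortly after the drop
— the shape real, diffusive-gated data has.

## Study conditions of the bundled reproductions

The reference experiments behind the acceptance checks run at the standard
parameters $\lambda = 1$, $A_0 = 40$, $k_BT = 1$ on a fluid-derived
disordered lattice. Full-scale scans (order $10^3$ cells, up to $10^6$
sweeps per state point) are not desk-scale, so the package's own
reproductions use a reduced system, chosen once:

* disordered lattice of 16 640 sites (fluid generator: 800 × 832 square
  lattice, 16 640 cells, $\alpha = 0.8$, 1 500–2 000 equilibration
  sweeps), rescaled to a 129.0² box — which is, conveniently, tileable by
  19 × 22 hexagons of area 39.8 to within 0.4%;
* ~416 cells (rectangular start) or 418 cells (hexagonal start);
* solid state: $\alpha = 2.6$, $2\times10^4$ waiting + $2\times10^4$
  sampling sweeps; fluid state: $\alpha = 1.8$, $1.5$–$2\times10^4$
  waiting + $4\times10^4$ sampling sweeps, two to three replicates pooled;
* scan: $\alpha \in \{1.7, 1.9, 2.0, 2.1, 2.2, 2.3, 2.5\}$, one replicate
  per point, $1.5\times10^4 + 2.5\times10^4$ sweeps, hexagonal starts
  above $\alpha = 2.2$.

At ~400 cells the transition indicators carry finite-size shifts of order
±0.1 in $\alpha$ and single-replicate statistical scatter of a similar
magnitude; the scan checks therefore test agreement *between* the
indicators tightly and their absolute location loosely. The shape-space
observables (the solid-state $n^\ast$ peak near 5.7, the fluid-state
interior minimum at $n^\ast \approx 5$) are local-geometry quantities and
are already stable at these sizes, although the interior minimum requires
a few hundred cells to resolve cleanly — at ~50 cells the fluid $n^\ast$
distribution does not reliably separate into two modes.

## What the synthetic generators do and do not emulate

The synthetic random-walk and ballistic trajectories validate the MSD
pipeline against exact closed forms; they contain no caging, so they say
nothing about the subdiffusive crossover of real runs. `synthetic_scan()`
plants idealized, noise-free transition signals; it validates the
estimators' numerics, not their statistical behavior under run-to-run
scatter. The fluid-derived lattice generator emulates the structural
properties that matter for the substrate (even site sizes, 4–10 neighbors
per site, no long-range orientational order); it does not emulate any
biological heterogeneity — lattices are monodisperse by construction.

## Known limitations

* No connectivity constraint: cells may transiently fragment at low
  surface tension. `fragmentation_report()` monitors this passively; runs
  in the solid state should (and do) show one component per cell.
* $\langle|\psi_6|\rangle$ from instantaneous centers saturates below 1
  in the solid at $k_BT = 1$ because of center-of-mass jitter (see
  above); comparisons with values read off published figures should keep
  this definition sensitivity in mind.
* The Metropolis proposal (uniform site, uniform neighbor) is not
  symmetrized by contact length on irregular lattices; as in the standard
  algorithm, "time" is Monte-Carlo time, not a physical clock.
* Perimeters of raw lattice cells are metric-inflated; all shape analysis
  goes through the Voronoi polygons of the centers, which is a modelling
  choice, not an approximation-free measurement.
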