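---
title: "Models and methods behind gelkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gelkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelkinetics)
```

# Scope

`gelkinetics` implements the analysis chain used to characterize water and
polymer dynamics in HEMA/VP hydrogel simulation cells: hydration
stoichiometry and cell sizing, radial distribution functions (RDFs),
geometric hydrogen-bond detection, probe free volume with
diffusion-channel labelling, mean-square-displacement (MSD) and
anomalous-exponent fitting, Einstein diffusion coefficients, van Hove
self-correlation with hopping-mode detection, and glass-transition
location from volume-temperature series. It does **not** run molecular
dynamics: force fields, thermostats, barostats and electrostatics are out
of scope. Instead, a family of stochastic generators produces
trajectories and configurations with *known ground truth* so that every
analysis stage is testable end to end.

Internal units are Angstrom and picoseconds. Diffusion coefficients are
accepted and reported in cm^2/s (1 A^2/ps = 1e-4 cm^2/s), the unit in
which water diffusion in hydrogels is conventionally quoted.

# Hydration stoichiometry

A simulation cell holds one 50-mer chain plus `n` water molecules. For a
target water mass fraction `f`, the stoichiometry is

    n = round( f / (1 - f) * M_chain / m_water ),   m_water = 18.015 g/mol,

rounded to the nearest integer (ties away from zero). The chain molar
mass is the bare sum of mer masses — HEMA (C6H10O3, 130.14 g/mol) and VP
(C6H9NO, 111.14 g/mol) from standard atomic masses — with end groups
excluded by default because capping chemistry is rarely reported; an
optional `end_group_mass` argument (about 16-18 g/mol for H/OH capping)
is available. The cubic cell edge at a target density `rho` is
`(M_total / (N_A rho))^(1/3)`. At the reference density of 1.1 g/cm^3
these formulas reproduce the published cell compositions of the
PHEMA/P(VP-co-HEMA) family at 10-40% water exactly; at 60% water the
printed counts sit one molecule above the bare-mass rounding, consistent
with a small unreported end-group mass.

The five named polymers follow the prose compositions: `H50` (50 HEMA),
`B37`/`R37` (37 HEMA + 13 VP, block/random), `B13`/`R13` (13 HEMA +
37 VP). Random sequences are drawn once from the stated counts with a
fixed internal seed so the composition — the only thing the
stoichiometry depends on — is exact and reproducible.

# Synthetic generators and what they emulate

The generators define the study conditions for the dynamic analyses.
Each is deterministic under a fixed seed and leaves the caller's RNG
stream untouched.

* **`genBrownian`** — i.i.d. Gaussian increments with per-axis variance
  `2 D dt`. Ground truth: MSD exponent `alpha = 1`, Einstein coefficient
  `D`. The default `D = 1.5e-5 cm^2/s` is a typical water diffusion
  coefficient in hydrated polymer cells.
* **`genFbm`** — fractional Brownian motion per axis, synthesized by
  exact-covariance circulant embedding (Davies-Harte) rather than
  approximate subordination, because the tests rely on exact scaling:
  `alpha = 2 H` over all lags.
* **`genCtrw`** — renewal walk with Pareto waiting times
  (`w = dt U^(-1/mu)`, `mu` in (0,1)) and Gaussian jumps. The *ensemble*
  MSD from the process origin grows as `t^mu`. CTRW ages: averaging over
  sliding time origins progressively linearizes the time-averaged MSD
  (weak ergodicity breaking), so exponent-recovery analyses for this
  generator use a single origin at `t = 0`. This distinction is real
  physics, not an implementation artifact, and is exercised in the test
  suite.
* **`genCageHopper`** — in-cage mean-reverting (discrete
  Ornstein-Uhlenbeck) fluctuation of stationary scale `cage_sigma` plus
  Poisson-timed center hops of fixed length. At lags near `1/hop_rate`
  the displacement distribution `4 pi r^2 G_s(r, t)` is bimodal with the
  second mode at the hop length — the hopping signature reported for
  low-hydration gels — and the long-time MSD gives jump diffusion
  `D = hop_rate * jump_length^2 / 6`. At high hop rates the modes merge
  into a single broad diffusive peak, mirroring the disappearance of
  hopping at high hydration.
* **`genRouse`** — overdamped Euler-Maruyama integration of phantom
  harmonic bead-spring chains (no excluded volume), equilibrium
  (Boltzmann bond-vector) start. Between the bond relaxation time
  `~zeta/(4k)` and the Rouse time `zeta N^2/(3 pi^2 k)` a middle bead
  subdiffuses with `alpha = 0.5`; a 1-bead chain is free Brownian. The
  stability bound `dt k/zeta < 0.25` is enforced.
* **`genPacking`**, **`genHbondFixture`**, **`genBilinearVT`** — static
  fixtures: simple-cubic/Poisson packings for RDF and free-volume
  checks, donor-hydrogen-acceptor triples realizing requested
  (D···A, H···A, deviation) geometries via the law of cosines, and
  two-segment linear volume-temperature series on the 650 to 200 K,
  25 K-step cooling grid.

What the generators do **not** emulate: molecular structure (bond
connectivity, torsions), polymer-water coupling, spatial heterogeneity
of real gels, and long-range correlations between particles. Passing
tests therefore demonstrate correctness of the *estimators* on processes
with known exponents and geometries, not fidelity of any particular
force field.

# MSD, exponent and diffusion estimation

`msd()` averages squared displacements over particles and sliding time
origins on a log-spaced lag grid (~20 points per decade), requiring
unwrapped coordinates; `unwrapTrajectory()` reconstructs continuous
paths by accumulating minimum-image frame-to-frame displacements and
refuses apparent jumps of half a box edge or more, which are ambiguous.

`fitPowerLaw()` performs least squares of `log MSD` on `log t` in an
explicit window; `MSD = K_alpha t^alpha`. Published fitting windows for
such data are often stated loosely, so no window is hard-coded: the
default is one decade centered (in log time) inside the available lags,
and analyses that care (e.g. the Rouse intermediate regime) pass an
explicit window. For the Rouse benchmark the window
`[5 tau_bond, tau_Rouse/5] = [1.25, 27.6]` (reduced time, `k = zeta = 1`,
N = 64) keeps about 1.3 decades clear of both crossovers.

`diffusionCoefficient()` implements the Einstein relation as
`D = slope/6` of the particle-averaged MSD. (A printed form that divides
by `6N` *after* the MSD has already been averaged over the N particles
double-counts N; the implementation is fixed by the Brownian limiting
case, which recovers the generator's `D`.) If the local exponent in the
fit window falls outside 0.9-1.1 the window is not in the linear regime
and the result carries a warning flag rather than an error.

# Van Hove self-correlation and hopping

`vanHoveSelf()` histograms displacement magnitudes per lag;
`gs` is a per-volume density normalized so the shell mass
`4 pi r^2 gs dr` sums to one at each lag, which makes the second-moment
identity `integral r^2 G_s dr = MSD(t)` hold by construction up to
binning resolution (tested to 1% with `dr = 0.05 A`). `detectModes()`
smooths the shell mass with a centred moving average (default 3 bins)
and keeps local maxima whose topographic prominence — height above the
key saddle toward the nearest higher point — is at least 5% of the
global maximum. The smoothing width and prominence threshold are fixed
defaults so mode counts are reproducible; they were chosen once as the
weakest smoothing that suppresses single-bin sampling ripple at the
sampling depths used in the tests (roughly 2-5 x 10^4 displacement
samples per lag).

# RDF, hydrogen bonds, free volume

All static analyses use the minimum-image convention in cubic periodic
boxes, valid up to `r_max = L/2`; no neighbor-list cutoffs are used at
these system sizes, so correctness never depends on cell-list bookkeeping.

`rdf()` normalizes shell counts by `N_pairs/V * 4 pi r^2 dr`, which makes
a Poisson gas read 1 and whose density-weighted integral returns the pair
count (both tested).

`detectHbonds()` applies the geometric D-H···A criteria: D···A <= 3.5 A
(inclusive), H···A < 2.5 A (exclusive), deviation from linearity
(180 degrees minus the D-H···A angle at the hydrogen) <= 30 degrees
(inclusive). The inclusive/exclusive reading follows the criteria's
wording ("3.5 A or shorter", "less than 2.5 A", "up to 30 degrees") and
is enforced with a 1e-9 A / degree floating-point guard so
exactly-at-threshold fixtures land on the intended side. Hydrogens are
associated to their covalent donor as the nearest donor within 1.3 A.
The conventional 1.2 A covalent-bond cutoff proved geometrically
inconsistent with boundary test fixtures: a triple with D···A = 3.5 A,
H···A = 2.4 A and 30 degrees deviation *requires* d(D-H) = 1.209 A by the
law of cosines, so the pairing radius was set to 1.3 A — comfortably
above any O-H/N-H bond length yet far below nonbonded H···O contacts
(>= 1.5 A). Detection is validated against an exhaustive all-triples
oracle on 50 random 200-atom configurations.

`freeVolume()` is a grid-probe (Connolly-style insertion) estimate: a
voxel center is free when farther than `r_vdW + r_probe` from every atom
(vdW radii: C 1.70, H 1.20, O 1.52, N 1.55 A), FFV is the percentage of
free voxels, and channels are connected components of free voxels under
periodic 6-connectivity — the standard, reproducible labelling choice.
Grid spacing must be at most `probe/2` (0.5 A for a point probe);
halving the spacing moves FFV by under 0.3 percentage points on the test
fixtures, and a single vdW sphere in a box matches the analytic volume
fraction to 0.2 points at 0.25 A spacing. Because published free-volume
tables rarely state grid resolution, FFV comparisons across codes should
be made on trends (monotone decrease with probe radius, increase on
stripping solvent), which is how the test suite treats them.

# Glass-transition fitting

`fitBilinear()` fits a *continuous* two-segment (hinge) model — two
lines constrained to intersect — because the breakpoint of two
independent lines is ill-defined when their fitted intersection drifts
outside the data. The breakpoint search is a grid over interior data
temperatures (excluding 3 points per edge so each segment keeps a
fittable sample) refined by golden-section minimization of the SSE
between neighbouring grid points; on noiseless bilinear data the fit is
exact regardless of breakpoint position. A series whose bilinear SSE
improves on a single line by less than 5% is flagged degenerate, and
`slope_above < slope_below` raises a physicality flag (a glass former
expands faster above Tg). An optional residual bootstrap supplies a
breakpoint standard error; it is off by default because the point
estimate does not need it. On the 19-point cooling grid with noise of
1% of the volume range, the breakpoint is recovered within half a grid
step (12.5 K) in well over 90% of 100 seeded replicates.

# Problem sizes and reproducibility

The test and benchmark sizes were chosen as the smallest ensembles whose
statistical error sits comfortably inside the stated tolerances: 500
walkers x 2000 steps for exponent and diffusion recovery (about 2-3
standard errors of margin at the ±0.05 / ±5% bands), 100 chains of 64
beads for the Rouse regime, 10^4-10^5 displacement samples per van Hove
lag, and 100 seeded replicates for the Tg recovery rate. Every stochastic
path is seeded explicitly; rerunning any generator, analysis or pipeline
config with the same seed reproduces results bit for bit (`runPipeline()`
records the config hash and seed in its JSON report).

# Known limitations

* Cubic boxes only; no triclinic cells.
* The free-volume estimator is voxel-based; it does not construct
  triangulated Connolly surfaces or solvent-accessible areas.
* Hydrogen-bond detection is geometric; no energetic or lifetime
  criteria.
* CTRW exponent recovery needs ensemble (fixed-origin) averaging, as
  discussed above; the package leaves the origin policy explicit rather
  than guessing.
* The Rouse integrator is Euler-Maruyama; its O(dt) discretization bias
  is negligible at the enforced stability bound but the integrator is
  not meant for stiff spring constants.
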