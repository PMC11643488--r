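# gelkinetics

Structure and transport analysis of molecular-dynamics trajectories of
water-swollen polymer networks — the kind of PHEMA / P(VP-co-HEMA)
hydrogel cells used for contact-lens materials — together with
stochastic trajectory generators with known ground truth, so the whole
analysis chain can be validated without access to any MD engine.

## Who it is for

Researchers analysing particle trajectories of hydrated polymers (or any
dense amorphous system) who need, in one tested R package:

* **Hydration stoichiometry** — water counts and cubic-cell edges for a
  polymer chain at a target water mass fraction and density:
  `n = round(f/(1−f) · M_chain / m_w)`, `L = (M_total/(N_A ρ))^{1/3}`.
* **Static structure** — radial distribution functions g(r) under
  periodic minimum image; geometric hydrogen bonds (D···A ≤ 3.5 Å,
  H···A < 2.5 Å, deviation from linearity ≤ 30°); grid-probe
  (Connolly-style) fractional free volume FFV with periodic
  6-connected diffusion-channel labelling.
* **Dynamics** — origin-averaged mean square displacement; the
  anomalous-diffusion law ⟨r²(t)⟩ = K_α t^α fitted on the log-log
  scale (α = 1 normal diffusion, α < 1 subdiffusion); Einstein
  diffusion D = (1/6) d⟨r²⟩/dt; the van Hove self-correlation
  G_s(r, t) with its second-moment identity
  ∫ r² G_s dr = ⟨r²(t)⟩ and multimodality ("cage hopping") detection.
* **Thermodynamics** — glass-transition temperature T_g from the
  breakpoint of a continuous bilinear fit of volume versus temperature.
* **Generators** — Brownian, fractional Brownian (α = 2H), heavy-tailed
  CTRW (α = μ), cage-hopping walkers, ideal Rouse bead-spring chains
  (middle-bead α = 0.5), lattice/Poisson packings, hydrogen-bond
  geometry fixtures and bilinear V(T) series, all seeded and exactly
  reproducible.

Trajectories are read and written as extended XYZ (box/time/wrap-state
metadata on the comment line); single configurations can also be read
from minimal PDB.

## Worked example

```r
library(gelkinetics)

## Hydration stoichiometry of the PHEMA homopolymer at 1.1 g/cm^3
hydrationTable("H50", c(0, 0.1, 0.2, 0.4))
#>   polymer water_pct n_water cell_edge achieved_pct
#> 1     H50         0       0  21.41653     0.000000
#> 2     H50        10      40  22.17957     9.969908
#> 3     H50        20      90  23.06511    19.946485
#> 4     H50        40     241  25.39485    40.019440

## Anomalous-exponent and diffusion recovery on Brownian walkers
tr    <- genBrownian(n_particles = 500, n_steps = 2000, dt = 1,
                     diffusion = 1.5e-5, seed = 42)
curve <- msd(tr, max_lag = 1000, origin_stride = 20)
fitPowerLaw(curve, window = c(10, 100))
#> PowerLawFit: alpha = 0.997, K_alpha = 0.9122 A^2/ps^alpha, window 10..100 ps (R^2 = 1.0000)
diffusionCoefficient(curve, window = c(100, 1000))
#> DiffusionResult: D = 1.45e-05 cm^2/s, window 100..1e+03 ps

## Hopping signature in the van Hove self-correlation function
hop <- genCageHopper(500, 500, cage_sigma = 0.3, jump_length = 3,
                     hop_rate = 0.02, seed = 7)
vh  <- vanHoveSelf(hop, lag_times = 50, dr = 0.1, origin_stride = 10)
detectModes(vh, lag = 50)
#> [1] 0.55 3.05

## Glass transition from a noisy volume-temperature series
fitBilinear(genBilinearVT(t_break = 425, noise_sd = 3.8, seed = 11))
#> TgFit: Tg = 418.63 K, dV/dT = 0.4809 (below) / 1.189 (above) A^3/K
```

Reading the output: 40 water molecules bring a 50-mer PHEMA cell to 10%
water by mass in a 22.2 Å cube; Brownian walkers fit α ≈ 1 and return
the input D = 1.5e-5 cm²/s within a few percent; the cage-hopping walk
shows a bimodal displacement distribution with the second mode at the
3 Å hop length; and the bilinear fit locates the 425 K breakpoint
within a fraction of the 25 K temperature step despite 1%-of-range
noise.

A config-driven pipeline (`runPipeline()`) chains generator and analysis
stages from a YAML file and writes tabular outputs plus a JSON report
with seeds and a config hash; `inst/cli/gelkinetics.R` exposes the same
functionality as shell subcommands (`hydrate`, `simulate`, `rdf`,
`hbond`, `freevol`, `msd`, `fit-alpha`, `diffusion`, `vanhove`, `modes`,
`tg`, `run`).

See `vignettes/hydrogel-dynamics.Rmd` for the models, parameter choices,
numerical conventions and limitations.

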