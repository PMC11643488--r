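Package: gelkinetics
Title: Structure and Transport Analysis of Hydrogel Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of
    water-swollen polymer networks such as HEMA/VP contact-lens hydrogels.
    Provides hydration stoichiometry and cubic-cell sizing from mer
    formulas, radial distribution functions under periodic boundaries,
    geometric hydrogen-bond detection, grid-based probe free volume with
    diffusion-channel labelling, mean-square-displacement and anomalous
    diffusion exponent fitting, Einstein diffusion coefficients, van Hove
    self-correlation functions with hopping-mode detection, and
    glass-transition estimation by continuous bilinear fits of
    volume-temperature series. Includes stochastic trajectory generators
    (Brownian, fractional Brownian, continuous-time random walk,
    cage-hopping, Rouse chains) with known ground truth, extended-XYZ and
    minimal PDB readers, and a config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
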