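Package: mrebdyn
Title: Mechanics and Curvature-Guided Translocation of Membrane-Bound Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models short, intrinsically curved protein filaments (such as the
    bacterial actin homolog MreB) bound to fluid membranes. Computes the free
    energy of filament-membrane binding as a function of binding angle, with
    membrane deformations obtained from the biharmonic shape equation solved by
    a two-Poisson finite element split, and classifies binding regimes. Simulates
    processive, stochastic filament translocation along directions of largest
    principal curvature on parametric surfaces (spherocylinders, tori, helices,
    ellipsoids, bulged, undulating and non-circular cylinders), solves the
    corresponding Fokker-Planck equation for the steady-state filament
    concentration with a metric-aware finite-volume scheme, and summarizes the
    resulting localization as region enrichment ratios, curvature-enrichment
    curves, bulge occupancies and per-hoop axial displacement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
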