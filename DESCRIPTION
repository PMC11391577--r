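Package: cgionfit
Title: Coarse-Grained Ion Model Parameterization and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for parameterizing coarse-grained (CG)
    sodium/chloride ion models against concentration-resolved bulk
    properties. Provides a reproducible CG molecular-dynamics engine with
    SPICA-style Lennard-Jones 9-6/12-4 pair potentials, screened
    electrostatics (Ewald or shifted cutoff), harmonic bonded terms,
    Nose-Hoover thermostats/barostats and semipermeable virtual walls;
    generators for bulk, slab, biphasic, osmotic-cell and toy-bilayer
    systems; estimators for mass density, Kirkwood-Irving surface and
    interfacial tension, virtual-wall osmotic pressure, area per lipid,
    headgroup-headgroup distance and acyl-chain order parameters with
    block-averaged uncertainties; and a two-condition fitting pipeline
    (Bayesian optimization of pair epsilon/sigma against density and
    surface-tension target curves, then targeted tuning of the
    sodium-chloride cross interaction against osmotic pressure).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
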