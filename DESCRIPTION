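Package: poreblock
Title: Pore-Block Binding Affinities and Dose-Response Modelling for
    Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing machinery for alchemical free-energy studies of
    anesthetic block of the pore of pentameric ligand-gated ion channels
    (GLIC and relatives). Provides absolute binding free-energy bookkeeping
    with standard-state, restraint-volume and symmetry corrections and
    interconversion with dissociation constants; bidirectional free-energy
    perturbation estimation via exponential averaging and the Bennett
    acceptance ratio; a two-site modified Adair pore-block dose-response
    model predicting IC50 ranges from microscopic stepwise affinities, with
    curve fitting; pore-geometry analyses (M2 helix pair distances,
    Boltzmann-transform profiles, flat-bottom restraint design, axial ligand
    density and site occupancy); and seeded synthetic-data generators with
    known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    bio3d,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
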