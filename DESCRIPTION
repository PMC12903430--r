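Package: pamcas
Title: Modular Dendrimer Construction Calculus, Nanofiltration Modelling,
    and Solution-Property Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modular poly(amide-carbosilane) dendrimer design and
    purification planning.  A building-block grammar enumerates layer
    sequences over branch modules of different multiplicity, computes
    peripheral-group counts, elemental compositions, average and
    monoisotopic masses, end-group defect mass ladders and SMILES
    encodings.  A constant-transmission model of organic solvent
    nanofiltration simulates batch and continuous diafiltration, plans
    cycle numbers for a target purity, and estimates per-cycle solute
    transmission from retentate series.  Solution-property analytics cover
    the radius of gyration and maximal radius of conformer point clouds,
    the shape factor against the hard-sphere reference, Stokes-Einstein
    conversions, log-log diffusion scaling exponents, and molar-mass
    dispersity.  Seeded synthetic-data generators provide filtration,
    diffusion, point-cloud and defect-ensemble fixtures with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
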