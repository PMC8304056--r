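Package: scattermd
Title: Scattering-Length-Density Profiles and Specular Reflectivity from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts membrane molecular-dynamics trajectories (PDB or GRO
    frames) into time-averaged number-density and scattering-length-density
    profiles along the bilayer normal, with post-hoc isotopic (H/D)
    substitution and solvent contrast variation.  Assembles free-floating
    bilayer profiles into measurable systems: a semi-infinite substrate with
    a rough native-oxide layer, adjustable substrate-membrane water gaps,
    lamellar multilayer tiling and disordered interlamellar-spacing
    ensembles.  Predicts specular neutron and X-ray reflectivity of slab
    stacks by exact Parratt recursion and Abeles transfer matrices with
    Nevot-Croce interfacial roughness, a Born-approximation cross-check,
    Gaussian resolution smearing, scale and background corrections, and
    Bragg-peak location.  Computes small-angle scattering of unilamellar
    vesicles from concentric-shell models with Schulz-Zimm core
    polydispersity and fits them to measured curves by weighted least
    squares.  Ships a synthetic-fixture generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
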