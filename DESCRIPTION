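Package: ablatesim
Title: Multiphysics Simulation of Multi-Antenna Microwave Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microwave ablation of large liver tumours with a
    sequentially repositioned single-slot coaxial antenna. Solves the
    time-harmonic electromagnetic wave (curl-curl) equation with lowest-order
    Nedelec edge elements on tetrahedral meshes, couples the absorbed power
    one-way into a Pennes bioheat solver with temperature-dependent effective
    specific heat, water content, thermal conductivity and an irreversible
    blood-perfusion latch, integrates a three-state (alive/vulnerable/dead)
    thermal cell-death model, evaluates a weighted temperature-time dose and
    localized tissue-contraction law, and reports ablation-volume and
    healthy-tissue damage accounting for multi-position heating protocols.
    Includes a structured graded phantom mesh generator, Gmsh MSH reading and
    writing, and VTU/CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
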