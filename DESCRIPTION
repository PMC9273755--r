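Package: stiffmap
Title: Peri-Cellular Stiffness Mapping by Optical-Tweezers Microrheology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis chain for optical-tweezers active and
    passive microrheology of the extracellular matrix around single cells.
    Generates synthetic quadrant-photodiode signals, bead trajectories,
    stiffness fields, fiber-network volumes and immunofluorescence stacks
    with known ground truth; extracts drive-frequency lock-in components,
    complex material stiffness and shear moduli (generalized Stokes and
    generalized Stokes-Einstein inversion of the mean-square displacement);
    maps stiffness into folded annular bins around a traced cell outline;
    sizes hydrogel pores by a 3D distance-transform watershed; quantifies
    nuclear/cytoplasmic YAP ratio, fibronectin partitioning and cell shape;
    and fits the multivariate exponential regression of stiffness on
    distance, angle and dummy-coded condition covariates together with the
    accompanying nonparametric tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
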