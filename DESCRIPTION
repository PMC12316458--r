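Package: lrflow
Title: Left-Right Organizer Flow and Asymmetry Phenotype Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for zebrafish left-right patterning
    studies: a multinomial permutation test for phenotype outcome
    distributions based on a total-variation-style dissimilarity, a
    uniform-prior Beta-binomial estimator of malformation probability, exact
    Fisher tests, reconstruction of integer counts from printed percentages,
    a microbead tracking pipeline for Kupffer's vesicle flow (blob
    detection, gated nearest-neighbour linking, mean-square-displacement
    analysis and directed/confined/diffusive motion classification), dorsal
    forerunner cell migration kinematics, and synthetic-data generators
    (multinomial tables, vortex/confined/Brownian bead trajectories,
    rendered fluorescence spot stacks, converging cell tracks) so that every
    stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
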