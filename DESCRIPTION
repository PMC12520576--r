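Package: capsulejet
Title: Electro-Mechanical Control of Compound Jet Breakup for Hydrogel Capsule Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing the production of monodisperse
    core-shell hydrogel capsules by piezo-actuated, electrified breakup of a
    compound alginate jet. Implements the viscous Plateau-Rayleigh dispersion
    relation, targeted droplet radii under periodic forcing, electric Bond
    number and whipping thresholds, a phase classification of the (wavenumber,
    charge) plane, and Poisson cell-loading forecasts; a seeded synthetic
    generator of ground-truthed beads-on-a-string high-speed movies and capsule
    micrographs; the video-analysis chain (jet-axis correction, fragmentation
    length, Canny + circular-Hough droplet sizing, kymographs, bead tracking,
    capsule segmentation); and population statistics (Gaussian-mixture radius
    fits, selectivity, coalescence-mode labelling, sweep tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mclust,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
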