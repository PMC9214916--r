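Package: molkde
Title: KDE-Binned Internal-Coordinate Molecular Representations for
    Energy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds explainable molecular feature vectors for small CHNO
    organic molecules from the kernel-density-estimate maxima of their
    bond-length, bond-angle, dihedral and hydrogen-bond distance
    distributions, and couples them with kernel ridge regression, neural
    network, linear and random-forest regressors to predict DFT-level
    electronic and free energies from (possibly force-field-quality) 3D
    geometries. Includes database curation filters, a
    stoichiometry-grouped train/test split, and distorted-replicate data
    augmentation with its associated distortion constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
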