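Package: toothfea
Title: Finite Element Analysis of Restored Teeth with Ceramic Dentin Inserts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale linear elastic finite element pipeline for comparing
    Class-I-like composite restorations with and without stiff hydroxyapatite
    dentin inserts. Builds parametric synthetic tooth geometries (enamel cap,
    dentin body, pulp chamber, periodontal ligament shell, supporting bone
    block) for five restoration scenarios, meshes them with region-tagged
    linear tetrahedra on a background grid, emulates polymerization shrinkage
    of composite and luting cement by a thermal analog (steady-state heat
    conduction followed by thermo-elastic loading), superposes a distributed
    occlusal force, and reduces the solution fields to region-wise von Mises
    stress statistics, displacement maxima, volumetric contraction rates and
    insert-versus-control percent decreases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
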