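Package: fibrekin
Title: Voxel-Based Finite Element Damage Kinetics in Plant Bast Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for simulating tensile damage in notched plant bast
    fibers (hemp, flax) from micro-tomographic voxel images. Generates
    synthetic two-phase fiber tomograms with lumen, notches and surface
    roughness; segments and quantifies porosity and cross-section
    morphometrics; converts solid voxels to an 8-node hexahedral finite
    element mesh with binary gray-level material mapping; solves the 3D
    linear elastic tensile problem with a matrix-free preconditioned
    conjugate-gradient solver; iterates stress-criterion element
    degradation to the ground stiffness level; and characterizes the
    resulting damage-ratio curves (onset, growth, saturation stages,
    growth-rate modality, criterion aggressiveness) together with
    identification of the solid-phase Young's modulus and Poisson ratio
    from force-displacement and lateral-contraction data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
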