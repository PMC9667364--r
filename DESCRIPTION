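Package: lensmorph
Title: Ocular Lens Shape Morphometrics and Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three-dimensional shape metrics (anisotropy, flatness,
    elongation, sphericity) and transverse diameters of ocular lenses from
    segmented voxel volumes, and tests ecological and ontogenetic hypotheses
    about lens shape with phylogenetic comparative statistics: phylogenetic
    generalized least squares with maximum-likelihood Pagel's lambda,
    multivariate phylogenetic signal (K_mult) with permutation inference,
    principal component analysis and Welch t-tests. Includes generators for
    voxelized lens phantoms, pure-birth phylogenies and trait tables with
    known effect sizes, so every stage of the analysis pipeline is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    nlme,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
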