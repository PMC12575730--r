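Package: ensemblefit
Title: Ensemble-Based Flexible Fitting of Protein Models into Cryo-EM
    Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines protein structures into cryo-EM density maps starting
    from a conformational ensemble rather than a single known structure.
    The pipeline filters ensemble members by a length-scaled geometry
    score, clusters the survivors (k-means on superposed C-alpha
    coordinates, or k-medoids on an internal-distance RMSD matrix),
    rigid-body fits cluster representatives into the target density,
    runs density-guided refinement with adaptive force scaling, and
    selects a final model by a compound score combining map
    cross-correlation and geometry quality. Includes MRC map I/O, map
    simulation from atomic models, a synthetic two-state fixture
    generator, and RMSD-based validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
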