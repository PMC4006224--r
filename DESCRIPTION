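Package: motiondiff
Title: Head Motion and White-Matter Diffusion Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how in-scanner
    head motion associates with white-matter diffusion MRI metrics.
    Generates synthetic multi-subject, multi-session diffusion-weighted
    cohorts with known motion/metric couplings; scores head motion as the
    mean RMS deviation of consecutive-volume rigid transforms; fits the
    diffusion tensor (FA, MD) and computes local diffusion homogeneity
    (Kendall's coefficient of concordance over voxel neighbourhoods);
    builds a mean-FA skeleton with perpendicular maximum-FA projection;
    quantifies test-retest reliability with the consistency intraclass
    correlation coefficient; and tests motion effects with permutation
    GLMs under threshold-free cluster enhancement with family-wise error
    control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
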