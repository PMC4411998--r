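Package: rootCT
Title: X-Ray CT Phenotyping of Developing Root Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the architecture of developing root
    systems from X-ray computed tomography volumes in Hounsfield units.
    The pipeline isolates root skeletons and volumes from plant-soil CT
    data by threshold-gated layer growing, estimates structural complexity
    as a 3-D cube-counting fractal dimension with a middle-sidelength
    subset rule, derives compartment volumes, skeleton lengths, relative
    growth rates and length increments over weekly scans, and tests
    group-by-week effects with epsilon-adjusted repeated-measures ANOVA.
    A synthetic phantom generator produces CT volumes of stochastic root
    architectures with voxel-level ground truth so every stage can be
    validated without physical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phenotyping, ImageAnalysis, Visualization
RoxygenNote: 7.3.3
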