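Package: vasculomorph
Title: Multimodality Vascular Morphometry and Perfusion Analysis for
    Preclinical Brain-Tumor Imaging
Version: 0.1.0
Authors@R:
    person("Vasculomorph", "Developers", email = "dev@vasculomorph.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying abnormal tumor vasculature
    across imaging modalities in small-animal studies: dynamic
    susceptibility contrast (DSC) MRI relative cerebral blood volume by
    delta-R2* curve integration, micro-CT vessel-tree morphometry (3D
    skeletonization, branch-graph extraction, branch density in
    branches/mm^3 and branching angle-to-length tortuosity in deg/mm),
    immunohistochemistry microvessel count and cross-sectional area
    morphometry, and exponential tumor growth kinetics. Includes a
    synthetic-data generator for every modality with known ground truth
    (gamma-variate bolus passage, branching vascular trees rasterized to
    voxel grids, stained-field images, noisy growth trajectories) plus the
    cohort statistics used to compare treatment arms (one-way ANOVA with
    Bonferroni post tests, unpaired t-tests, exact and approximate
    Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
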