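Package: voxlmm
Title: Mass-Univariate Linear Mixed Models for 3-D Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxel-wise restricted maximum likelihood (REML) estimation and
    inference for linear mixed models fitted independently at every voxel of a
    set of co-registered 3-D images. Estimation uses Full Simplified Fisher
    Scoring expressed entirely in compressed cross-product ("product form")
    matrices whose size is independent of the number of input images, with
    image-wise map-reduce accumulation, voxel-wise missingness handled by
    zero-ing design rows, Wald T/F tests with Welch-Satterthwaite degrees of
    freedom, Bonferroni and Benjamini-Hochberg correction, and mixture
    chi-squared likelihood-ratio tests for random effects. Includes a
    synthetic-data generator producing smoothed, edge-masked image sets and a
    slow dense-matrix REML oracle for validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
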