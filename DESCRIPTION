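Package: hsrecon
Title: Hyperspectral Reflectance Reconstruction from Few-Band Multispectral Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates high-resolution vegetation reflectance spectra from
    few-band multispectral sensor readings. A dictionary of spectral atoms is
    learned from hyperspectral training data with K-SVD (orthogonal matching
    pursuit sparse coding plus rank-one singular-value atom updates) and
    spectra are recovered from band-subsampled measurements with the smoothed
    L0 (SL0) compressed-sensing solver. Two baselines are included: joint
    reconstruction of heterogeneously sampled sensor groups under the JSM-1
    joint sparsity model with first-difference sparsifying transforms and
    group-median aggregation, and universal pattern decomposition (least
    squares unmixing onto water, vegetation and soil base spectra). Band-set
    selection by rejection, a median-of-medians RMSE evaluation protocol,
    a synthetic vegetation scene generator with red-edge endmembers, and
    readers and writers for spectral library CSV and ENVI cubes round out the
    toolkit.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
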