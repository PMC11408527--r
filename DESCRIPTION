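Package: clawfc
Title: Functional-Connectivity Analysis of Hallucinogen Challenges in
    Ultrasound and Neuropixels Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chains for pharmacological functional ultrasound
    (power-Doppler CBV change and sliding-window regional connectivity)
    and dual-probe Neuropixels recordings (windowed unit-pair
    correlations, static and difference connectivity matrices, per-unit
    effect summaries with nonparametric group tests), together with an
    optical-density line-profile quantifier for in situ hybridization
    autoradiographs and seeded synthetic-data generators that emulate
    all three recording modalities for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    pracma,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
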