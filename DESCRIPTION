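Package: hsiSimilarity
Title: Spectral Similarity Measures and Annotation Quality Control for
    Medical Hyperspectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating labeled tissue spectra from medical
    hyperspectral images using spectral similarity measures. Implements the
    classical measures (spectral angle mapper, spectral information
    divergence, spectral correlation angle, Jeffries-Matusita distance),
    their tangent-hybrid combinations including SID-JM-TAN(SAM) and
    SID-JM-TAN(SCA), and the relative spectral discriminatory power,
    probability and entropy statistics used to compare measures across
    units. Provides a K-means-cluster, threshold-based procedure for
    checking and correcting tissue annotations, patient-wise
    cross-validation harnesses (leave-one-patient-out and grouped k-fold),
    a Savitzky-Golay / standard-normal-variate / min-max preprocessing
    chain, spectral library input/output, and a deterministic synthetic
    tissue-spectrum generator for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
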