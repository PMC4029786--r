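Package: RosetteGrowth
Title: Overlap-Corrected Rosette Area Estimation and Logistic Growth
    Analysis from Top-View Plant Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput growth phenotyping of rosette plants
    (such as Arabidopsis thaliana) from time series of single top-view
    grayscale images. Plant area is estimated with an explicit correction for
    leaf overlap: the plant center is located from the orientation lines of a
    few non-overlapping leaves, leaf tips are detected as local maxima of a
    smoothed polar radius profile about the center, per-leaf areas are
    inferred from a piecewise (linear/exponential) leaf length-to-area model
    selected by a curvature ratio, and the summed leaf area is combined with
    the observed top-view area into an overlap-corrected plant area. The
    resulting area series is fitted with a three-parameter logistic growth
    model by nonlinear least squares, from which absolute and relative growth
    rates, growth velocity and acceleration, and phase-plane features
    (acceleration-versus-velocity loop extrema and enclosed area) are
    derived. A synthetic-rosette generator with exact polygon ground truth
    supports validation, and an evaluation harness reports tip recovery,
    area error and center distance against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    mclust,
    jsonlite,
    yaml,
    withr,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
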