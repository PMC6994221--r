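Package: ryrspat
Title: Spatial Analysis of Cardiac RyR2 Tetramer Arrays and Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the spatial organisation of type-2
    ryanodine receptor (RyR2) tetramers in cardiac dyads and on myocyte
    surfaces. Implements square-particle pair geometry and the
    checkerboard/side-by-side/isolated arrangement classifier for
    electron-tomogram tetramer maps, nearest-neighbour distance
    statistics, a dSTORM localization pipeline (blink quality control,
    10-nm rasterization, 50-nm linkage clustering, Delaunay alpha-shape
    areas, tetramers-per-cluster estimation), the k-sample
    Anderson-Darling comparison of distributions, and hierarchical
    (rat/cell/spark) bootstrap comparison of calcium-spark parameters
    with Holm-Bonferroni correction. Includes synthetic-data generators
    that emulate tetramer arrays, blink clouds and nested spark tables
    so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
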