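Package: fstatpca
Title: F-Statistics and Their Geometry in Principal Component Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Patterson F-statistics (f2, f3, f4) from population
    allele frequencies and links them to principal component analysis.
    Population allele frequencies are treated as points in Euclidean allele
    frequency space, where f2 is a squared distance and f3/f4 are dot
    products of difference vectors. The package obtains principal
    components either from the centred frequency matrix (SVD) or from the
    pairwise f2 matrix (classical multidimensional scaling via double
    centring), decomposes any F-statistic into per-PC contributions with an
    explicit truncation error, and provides geometric diagnostics: the
    admixture-f3 circle, outgroup-f3 ranking as a projection, the f4
    angle/correlation, f4-ratio admixture proportions, reference-axis
    residual rotation, and projection of new samples onto a reference PCA
    with its projection error. A simulator for allele frequencies evolving
    on trees and admixture graphs supports testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
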