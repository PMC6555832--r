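Package: oncochrom
Title: Modelling Oncohistone-Driven Redistribution of H3K27me3
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how K27M oncohistone incorporation reshapes
    the H3K27me3 landscape in a genome with one X chromosome and several
    autosomes. Implements binned ChIP-signal processing (bedGraph I/O,
    equal-total scaling, input subtraction or log2-ratio normalization,
    smoothing, re-binning), classification of the genome into four H3K27me3
    fate categories, hierarchical clustering of 10 kb bin triplets, a
    Taylor-polynomial dependency model linking pre-existing H3K27me3 and
    oncohistone levels to mutant H3K27me3 (evaluation with packaged
    coefficients and identifiable least-squares fitting), integration with
    expression quintiles and differential-expression calls, DAPI-anchored
    ploidy estimation, and a seeded synthetic-data generator emulating the
    chromatin structure of the worm germ line.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
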