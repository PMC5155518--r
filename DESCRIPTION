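Package: qtxmap
Title: Mixed Linear Model Association Mapping of Omics Variants with
    Epistasis and Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping of quantitative trait SNPs (QTS) and
    quantitative trait transcripts/proteins/metabolites (QTT/P/M) with a
    mixed linear model that treats all genetic terms -- additive main
    effects, additive-by-additive epistasis, and their environment
    interactions -- as random effects. Provides one-dimensional and
    two-dimensional genome scans based on Henderson method III reductions
    in sums of squares, experiment-wise significance by within-environment
    max-F permutation, stepwise assembly of the final candidate model,
    MINQUE(1) variance component estimation with adjusted unbiased
    prediction (AUP) of individual effects, Gibbs sampling of the mixed
    model equations, and a recombinant inbred line (RIL) simulator for
    power and unbiasedness experiments on a BXD-like genetic map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
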