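Package: morphodisp
Title: Morphospaces, Disparity Through Time and Phenotypic Complexity
    from Discrete Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying phenotypic disparity across deep time
    from discrete morphological character matrices and time-calibrated
    phylogenies. Implements Mk-model likelihoods, stochastic character
    mapping and phylogenetic imputation of missing tip states across a
    posterior tree sample; Gower and Euclidean dissimilarities aware of
    missing and inapplicable states; non-metric multidimensional scaling
    and principal coordinates morphospaces with reconstructed ancestral
    nodes; clade disparity indices with bootstrap envelopes and
    time-sliced disparity-through-time curves under gradual and
    punctuated models; presence-sum phenotypic complexity scores with
    phylogenetically corrected correlations against ploidy history; and
    a synthetic-data generator with known truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    stats,
    utils,
    jsonlite
Suggests:
    vegan,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
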