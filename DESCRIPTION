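Package: cladeforest
Title: Reconciling Parasite Phylogenies with Host and Biogeographical
    Metadata by Parsimony Optimization and Random-Forest Clade Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether categorical host-taxonomy and
    biogeographical metadata carry phylogenetic signal for a parasite tree.
    Provides Fitch/Hartigan parsimony optimization of categorical characters
    on rooted (possibly polytomous) trees with ACCTRAN/DELTRAN
    reconstructions and classification of nonambiguous transformations as
    unique, private or nonprivate synapomorphies; random-forest prediction
    of clade membership from one-hot encoded metadata under an escalating
    label-perturbation null with accuracy-degradation regression and
    feature-importance tracking; rooted-tree clade comparison; metadata
    curation and encoding; and a synthetic-data generator producing trees
    with planted monophyletic clades and clade-correlated hierarchical
    metadata for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    ranger,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
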