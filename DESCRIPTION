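Package: biomon
Title: Biomonitoring Indices for Community Data with Heterogeneous
    Taxonomic Resolution
Version: 0.1.0
Authors@R: person("biomon", "developers", role = c("aut", "cre"),
    email = "biomon@example.org")
Description: Tools for freshwater biomonitoring and community ecology:
    validation of taxonomic reference datasets, matching of community
    tables against them (with misspelling suggestions), aggregation of
    mixed-resolution data to every taxonomic rank, richness and
    diversity indices, sensitivity-score biotic indices (BMWP, ASPT,
    WHPT, LIFE, PSI, EPSI, EPT, EPTD, 1-GOLD, DEHLI, IBMR,
    biocontamination) with pluggable score tables and full traces,
    fuzzy-coded trait management, trait-space construction (Gower
    dissimilarity, principal coordinates with Cailliez, Lingoes,
    square-root and quasi-Euclidean corrections, axis-selection quality
    criteria), functional diversity indices (FRic, FDis, FEve, Rao's Q,
    redundancy, CWM, CSI), indicator-taxon analysis with permutation
    tests, plot-ready data structures, synthetic data generators and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
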