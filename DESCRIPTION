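Package: mbInherit
Title: Vertical Transmission of Host-Associated Microbiomes Across Colony
    Pedigrees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify vertical transmission of gut bacteria across
    social-insect colony pedigrees from 16S amplicon sequence variant (ASV)
    tables. Implements a strict presence-based inheritance classification
    (parental colony, all founding reproductives, at least one offspring
    colony sample), biparental attribution, pedigree-sharing and genus-overlap
    summaries, an abundance-weighted resampling null model with permutation
    p-values, within-genus abundance centering with a signed-log
    visualization transform and a stratified permutation association test,
    and categorical (inheritance-label) assortativity of signed ASV
    co-occurrence networks against null label assignments. A synthetic
    pedigree-data generator with planted ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    biomformat,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, Classification, Network
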