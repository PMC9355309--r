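Package: tipDNB
Title: Dynamic Network Biomarker Analysis for Ordered-Condition Expression
    Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the critical ("pre-disease") transition group in an
    ordered-condition transcriptome time course, such as graded
    ischemia/reperfusion kidney injury, via the dynamic network biomarker
    (DNB) composite index: per-group selection of high-variance genes,
    Pearson-correlation clustering at a fixed threshold, and the composite
    index mean_SD * PCC1 / PCC0 whose peak marks the tipping point.
    Supporting stages cover threshold-based differential-expression
    screening against a reference group, fuzzy c-means clustering of
    standardized temporal profiles, weighted running-sum gene-set
    enrichment with permutation nulls and leading-edge key-gene screening,
    qPCR 2^-ddCt fold changes, and a negative-binomial synthetic-data
    generator with planted differential expression, temporal profiles,
    enriched gene sets, and a planted DNB module for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    fgsea,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'deg.R'
    'dnb.R'
    'gsea.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
    'softclust.R'
    'utils.R'
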