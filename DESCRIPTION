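Package: pairscan
Title: Pattern-Based SNP-SNP Interaction Scanning with Cluster-Effect
    Diagnostics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects SNP-SNP interactions associated with a binary outcome by
    fitting, for every SNP pair, a catalog of 45 logistic interaction patterns
    built from four model structures, three inheritance modes (additive,
    dominant, recessive) and two allele-coding directions, and selecting the
    best pattern by the Bayesian information criterion. Provides best-mode
    main-effect tests, the three-p-value significance rule (3pRule), bootstrap
    selection-frequency validation, Hardy-Weinberg genotype simulators with
    effect-size calibration to target interaction p-values, and hub-SNP
    cluster diagnostics (true/false identification rates, cluster-level false
    positive rates, pair-correlation and linkage-disequilibrium summaries)
    for studying the cluster effect behind false-positive interaction calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: SNP, GeneticVariability, StatisticalMethod, Epistasis
RoxygenNote: 7.3.3
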