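Package: pleioscan
Title: Pleiotropy Mapping for Quantitative Traits via Multi-Trait
    Meta-Analysis and Gene-Based Monte Carlo Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pipeline for detecting pleiotropic loci and genes from
    single-trait genome-wide association scans on deregressed breeding
    values. Implements weighted polygenic (GBLUP-type) null models with
    leave-one-chromosome-out genomic relationship matrices and mmscore-type
    single-marker tests, a multi-trait chi-square meta-analysis with a
    diagonal-corrected t-value correlation matrix and an empirical
    false-discovery-rate threshold rule, and a VEGAS-style gene-based test
    with an adaptive Monte Carlo null respecting local linkage
    disequilibrium. A synthetic-data module generates LD-blocked genotypes,
    gene annotations and deregressed-EBV tables with known pleiotropic
    architecture so the whole pipeline runs end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
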