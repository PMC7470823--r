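Package: modqtl
Title: Trans-eQTL Discovery for Co-Expression Module Eigengenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects trans-acting expression quantitative trait loci for
    co-expression module eigengenes. Provides synthetic genotype/expression
    generators with planted effects, eigengene construction under clustering
    and matrix-factorisation paradigms, covariate-adjusted genome-wide scans,
    sum-of-single-effects Bayesian fine mapping with credible sets, graph-based
    aggregation of overlapping credible sets into non-overlapping loci, a
    cis-contamination filter based on gene-level trans associations,
    Benjamini-Yekutieli and Bonferroni multiplicity control, hypergeometric
    gene-set enrichment, and bootstrap causal mediation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
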