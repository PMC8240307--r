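Package: teqtl
Title: Translational Efficiency QTL Mapping in Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps local and distant quantitative trait loci for mRNA expression,
    ribosome occupancy, and translational efficiency (TE) across a panel of
    recombinant inbred lines. Collapses biallelic marker genotypes into strain
    distribution patterns (SDPs), jointly normalizes paired mRNA-seq and
    Ribo-seq count matrices, derives per-gene TE traits as residuals of
    regressing normalized ribosome footprint counts on normalized mRNA counts,
    and scans every trait against every SDP with stratified Benjamini-Hochberg
    and permutation-based empirical significance. Distant master-regulatory
    hotspots are detected with a hierarchical Bayesian variable-selection
    sampler using a multiplicative gene-by-locus inclusion prior and a
    two-component beta-mixture FDR on posterior inclusion probabilities.
    Includes standardized major axis regression of coding-sequence-length
    effects on expression fold changes, sarcomere thin-filament stoichiometry
    from footprint counts, and a synthetic-panel generator with planted,
    recoverable effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DESeq2,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
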