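Package: transrep
Title: Trans-Ethnic Replicability Analysis for Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well disease associations discovered in
    genome-wide association studies (GWAS) of one ancestry replicate in
    another. Provides curation filters for discovery/replication record
    tables (significance thresholds, 200-kb region pruning, MHC exclusion,
    risk-allele referencing), analytic replication power for case-control
    allelic tests under a log-additive model, power-adjusted (effective)
    replicability statistics with binomial null tests and publication-bias
    bounds, cross-ancestry effect-size concordance (Spearman correlation,
    log odds-ratio regression, windowed replicability profiles), and a
    varLD-style comparison of linkage-disequilibrium patterns between two
    populations in sliding SNP windows with permutation p-values and
    MAF-matched genomic backgrounds. Includes synthetic-data generators for
    replication databases with known causal-variant sharing and for
    two-population phased haplotype panels with tunable Wright-Fisher drift.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
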