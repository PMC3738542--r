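Package: fermscope
Title: Comparative Batch-Cultivation Physiology and Two-Colour Omics for
    Escherichia coli Production Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of Escherichia coli production
    strains grown in high-glucose batch culture. Provides a deterministic
    Monod batch simulator with acetate overflow and re-uptake kinetics,
    process metrics (log-linear growth rates, replicate summaries, substrate
    yield coefficients with acetate correction, elemental carbon balances),
    a reference-design two-colour microarray pipeline (MA statistics,
    print-tip loess normalisation, dye-swap consolidation, empirical-Bayes
    moderated t statistics, differential-expression filtering and Venn
    partitioning over a cross-platform common gene set), 2D-DIGE
    internal-standard ratio analysis with signed fold-change conventions,
    transcript-protein concordance calls for pairwise strain contrasts,
    functional-category tallies, and an end-to-end pipeline driver. Synthetic
    data generators with known ground truth make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
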