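Package: modulescout
Title: Discovery and Scoring of Paired-Motif Regulatory Modules in
    Promoter Regions
Version: 0.1.0
Authors@R:
    person("Module", "Scout Developers", email = "modulescout@example.org",
           role = c("aut", "cre"))
Description: Scans gene upstream regions for regulatory motifs given as
    IUPAC consensus strings, pairs motif occurrences into cis-regulatory
    modules, and scores modules with five statistics (component motif
    significance in bits, an area-between-curves spacing statistic against
    a shuffling null, a positional-bias statistic, gene-set coverage, and
    strand-orientation preference) combined into a normalized module
    score.  Includes downstream analyses (positional quartiles, group
    attribute aggregation, orientation-based gene partitioning with
    hypergeometric term enrichment, greedy extra-gene search), a
    synthetic-promoter generator with planted modules for validation, and
    a subcommand-style command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
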