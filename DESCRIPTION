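Package: lncnet
Title: lncRNA-mRNA Differential Expression, Positional Classification and
    Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of paired lncRNA/mRNA expression profiles
    from tumor versus normal cohorts: fold-change, Welch-test and
    Benjamini-Hochberg FDR filtering of differentially expressed genes;
    six-way positional classification of lncRNAs relative to protein-coding
    genes from GTF annotation; Pearson-correlation lncRNA-mRNA co-expression
    networks with degree-based hub ranking and pathway-seeded sub-networks;
    Fisher exact gene-set enrichment with a shared-gene pathway-act network
    and a sign-consistency activation score; and 2^-ddCt relative
    quantification of qPCR validation data. Includes a synthetic-data
    generator that plants known differential expression, correlation
    structure, positional categories and pathway overlaps for end-to-end
    recovery testing, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
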