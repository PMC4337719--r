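Package: cncnet
Title: Coding-Noncoding Coexpression Network Analysis for Small-Sample
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression for small two-group microarray designs
    using the random variance model moderated t-test, classification of cis
    lncRNA-mRNA pairs (overlapping, antisense, upstream, downstream within a
    configurable genomic window), construction of per-group coding-noncoding
    coexpression networks from Pearson correlations with k-core decomposition
    and differential-connectivity (diffK) hub ranking, and Fisher/chi-squared
    over-representation analysis with Benjamini-Hochberg false discovery rate
    control. Includes a fully seeded synthetic-data generator with known
    ground truth (planted differential genes, cis pairs, and differential-hub
    coexpression modules) so the whole pipeline can be exercised and validated
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    fgsea,
    GenomicRanges,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
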