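Package: srnakit
Title: Small RNA Sequencing Profiling, Protocol Detection and Conservation Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline toolkit for small RNA sequencing analysis: automated
    library-preparation protocol detection (3' adapter and randomized-end
    inference), low-complexity read filtering, full-length ungapped
    k-mismatch read alignment, hierarchical assignment of reads to ordered
    ncRNA annotation libraries, attribution of unmapped reads to grouped
    microbial genome collections, species disambiguation of BLAST tabular
    hits, positional consensus of miRNA target predictions, and
    conservation-depth estimation of small RNA sequences across genome
    collections.  A seeded synthetic-data generator provides ground truth
    for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
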