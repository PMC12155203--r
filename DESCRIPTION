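Package: tdrprofiler
Title: Small RNA Classification and tRNA-Derived RNA Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical small-RNA read classification (rRNA, miRNA, tRNA,
    piRNA, endo-siRNA, mRNA fragments) with class-priority assignment,
    reads-per-million normalization under genome, genome-minus-rRNA and
    per-class denominators, tRNA-derived RNA (tDR) metrics (anticodon-relative
    5'/3' half assignment, length by first-nucleotide matrices, per-isoacceptor
    coverage, >30/<30 nt size splits), strict 22G/26G endogenous siRNA
    extraction, single-embryo differential expression with coordinated
    gene-group shift analysis, and survival statistics. Includes a synthetic
    small-RNA library and single-embryo count-table generator with recorded
    ground truth so the whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
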