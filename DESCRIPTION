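Package: ernascope
Title: Enhancer Annotation, eRNA Calling and Chromatin Dynamics from
    Peak and Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates enhancers from p300 peaks using H3K4me1/H3K4me3
    co-occurrence and TSS-proximity rules, quantifies bidirectional
    enhancer RNA (eRNA) in strand-specific windows around peak summits
    with a set of exclusion filters, calls stimulus-inducible genes and
    enhancers, assigns extragenic enhancers to target genes within
    CTCF-delimited blocks, and quantifies condition-dependent binding-site
    occupancy and input-normalized promoter histone-methylation dynamics.
    Includes a seed-deterministic synthetic-data generator with a ground
    truth manifest for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
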