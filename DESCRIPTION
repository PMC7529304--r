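Package: mmejscan
Title: Genome-Wide Detection of Microhomology-Mediated End-Joining
    Signatures in Indel Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores insertion/deletion calls from paired pre-/post-
    transformation samples for signatures of microhomology-mediated
    end-joining (MMEJ) repair. Deletions are scored for junction
    microhomology against the downstream reference flank and stratified
    over minimum-microhomology thresholds; small (1-3 bp) insertions are
    classified as templated-in-trans events by searching the +/-15 nt
    sequence context for a repeated junction word; large (>= 18 bp)
    insertions are classified as snapback-synthesis events by searching
    the inserted sequence for internal inverted repeats. Enrichment of
    each signature in newly arisen versus pre-existing indels is tested
    with a continuity-corrected two-proportion chi-squared test. A
    synthetic-cohort simulator with a ground-truth manifest makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
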