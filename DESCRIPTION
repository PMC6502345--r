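Package: ffpeqc
Title: Quality Control and Feasibility Metrics for RNA-Seq of Archival FFPE Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-distribution metrics (DV200/DV100/DV50) computed from
    fragment-size distributions and size-calibrated electropherogram traces,
    a validated per-sample QC data model for degraded formalin-fixed
    paraffin-embedded (FFPE) RNA, pairwise-complete correlation and
    storage-time cohort analyses, expression-level concordance and artifact
    metrics (low-expression filtering, replicate correlation, signature-gene
    concordance clustering, gene-body coverage bias, GC-profile anomalies),
    an auditable go/no-go decision policy for library preparation and
    sequencing, and a synthetic-cohort generator with known ground truth for
    end-to-end validation of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
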