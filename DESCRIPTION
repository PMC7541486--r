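Package: episcope
Title: Subtype-Resolved Impact Scoring for Case/Control Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how strongly each transcriptomic cell
    subtype is affected by a disease condition in annotated case/control
    single-nucleus RNA-seq cohorts. Implements a centroid-correlation
    expression-similarity score with a robust control baseline (trimmed mean
    and MAD), pseudobulk differential expression with post-filters and
    gene-list Fisher enrichment, GO-term over-representation with
    Jaccard-based term clustering and cross-subtype collapse, a permutation
    test for cell-type composition shifts, a weighted ordinal six-metric
    impact score, resampled consensus co-expression module detection with
    intramodular-connectivity refinement and a four-stage filter cascade,
    and intensity normalization for single-molecule FISH quantification.
    Ships a synthetic-cohort generator with planted ground truth so the
    whole pipeline is testable without controlled-access patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    uwot,
    mclust,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
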