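Package: fibroscreen
Title: Screening Triage and Multi-Omics Follow-Up for Anti-Fibrotic Compound Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for triaging natural-compound libraries against
    an anti-fibrotic phenotype and following candidates up with targeted and
    global expression profiling. Covers plate-level screening quality control
    (Z-prime, signal window, signal-to-background, signal-to-noise) with
    plate/screen acceptance rules, four-parameter logistic dose-response
    fitting with effective concentrations at arbitrary effect levels and
    confidence intervals, activity calling and therapeutic indices with
    censoring, weighted ADMET prediction scoring and rank-product candidate
    selection, path-based chemical fingerprints and Tanimoto similarity,
    scratch-assay migration indices, two-stage adaptive FDR control
    (Benjamini-Krieger-Yekutieli) alongside BH/BY, qPCR-array (cT) filtering
    and discovery analysis, reference-gene normalized panel differential
    expression with shared-DEG set logic and pathway signature scores, and
    CPM filtering with TMM library-size normalization for RNA-seq style
    counts. Every input can be simulated with known ground truth by the
    bundled generators, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    ChemmineR,
    knitr
Config/testthat/edition: 3
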