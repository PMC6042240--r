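Package: fibrosig
Title: Control-Standardized Gene-Signature Scoring and Stratification of
    Fibrotic Skin Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes single-sample, direction-weighted gene-signature
    scores standardized against a healthy-control reference (per-gene
    z-scores summed with +1/-1 direction weights and centred on the
    control mean), with coefficient-of-variation and FDR-based signature
    gene filtering. Provides anchor-gene Spearman coexpression module
    discovery with pathway gene-set (GMT) intersection, hierarchical
    clustering of biopsies with chi-square tests of cluster-by-diagnosis
    association, score-score and score-clinical correlation and subgroup
    comparison utilities, cohort summary tables, and a latent-factor
    synthetic expression generator with planted axis correlations for
    end-to-end validation. A single-call pipeline orchestrates filtering,
    scoring, clustering and association into a reproducible JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
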