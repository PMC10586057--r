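Package: evsyn
Title: Evidence Synthesis for Replicated Genetic Association Findings in
    Depression and Antidepressant Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for synthesising curated case-control genetic
    association evidence for major depressive disorder susceptibility and
    antidepressant response. Recomputes allelic odds ratios, Woolf
    confidence intervals and chi-square p-values from raw genotype or
    allele counts, harmonises each study's reported risk allele to a
    common direction, identifies variants and genes replicated across
    candidate-gene and genome-wide studies, applies a minor-allele
    frequency filter, classifies risk-allele consistency, pools 2x2
    risk-allele confusion tables across concordant studies to estimate
    sensitivity, specificity and positive predictive value, summarises
    static functional annotations, and derives a shortlist of replicated
    single-risk-allele variants. Includes a synthetic catalog generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
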