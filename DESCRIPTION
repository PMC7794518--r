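Package: ctdnapipe
Title: Circulating Tumor DNA Somatic Variant Filtering, Tumor Fraction,
    TMB and Tissue Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for clinical-genomic analysis of
    circulating tumor DNA (ctDNA) from targeted panel sequencing of
    metastatic urothelial carcinoma and related cohorts. Implements
    matched-germline somatic variant filtering with mapping-quality and
    read-end proximity gates, conservative tumor fraction estimation from
    the highest somatic variant allele fraction using an exact binomial
    lower confidence bound and a loss-of-heterozygosity transform,
    depth-aware tumor mutational burden extrapolation from targeted
    panels, purity-corrected per-gene copy number with baseline-derived
    confidence intervals, and tissue versus plasma / serial sample
    mutation concordance statistics with exact contingency tests. A
    synthetic cohort generator with known ground truth (clonal structure,
    tumor fractions, germline and clonal hematopoiesis confounders, FFPE
    artifacts, amplified oncogenes) makes every stage testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
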