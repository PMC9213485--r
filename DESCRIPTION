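Package: ailqtl
Title: QTL Mapping and Candidate-Gene Prioritization for Advanced
    Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-marker quantitative trait locus (QTL) mapping for
    advanced intercross line (AIL) mouse populations: marker quality
    control, per-trait covariate screening, covariate-adjusted linear-model
    scans with genomic-control (lambda) correction, simpleM
    effective-number-of-tests Bonferroni LOD thresholds, 1.5-LOD-drop
    support intervals, and cofactor multiple-QTL mapping (MQM).  Companion
    stages cover Spearman phenotype correlation with family-wise
    correction, two-group differential expression on array-style
    intensities (log2, quantile normalization, t-tests,
    Benjamini-Hochberg), and a variant-consequence decision tree that
    scores and ranks positional candidate genes.  A forward simulator of
    AIL pedigrees, genotypes, phenotypes, expression and variant
    annotations makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
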