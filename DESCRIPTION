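Package: tissuespec
Title: Tissue-Specificity Classification of Gene Expression Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein-coding genes into six mutually exclusive
    expression-specificity categories (tissue enriched, group enriched,
    tissue enhanced, expressed in all, mixed, not detected) from a gene x
    tissue FPKM matrix, using a detection cutoff and fivefold enrichment
    rules. Includes replicate-to-tissue aggregation, cross-atlas
    concordance analysis (category cross-tabulation, expressed-in-all
    overlap, per-tissue elevated-gene agreement under a tissue mapping),
    interindividual coefficient-of-variation comparison between
    ubiquitously expressed and other genes (Mann-Whitney U), and a
    synthetic atlas generator with planted category structure and
    dispersion contrasts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
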