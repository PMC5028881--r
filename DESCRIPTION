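Package: ph1kit
Title: Variant Pathogenicity Scoring and Pedigree Analysis for Primary
    Hyperoxaluria Type 1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-side genetic workup of primary hyperoxaluria
    type 1 (PH1) families. Implements a combined Grantham-distance and
    multiple-sequence-alignment conservation rubric that classifies AGXT
    missense variants as high, moderate or probably non-pathogenic;
    Mendelian-consistency checking, cis/trans phasing of tightly linked
    variants and autosomal-recessive co-segregation testing on pedigrees;
    control-cohort minor-allele-frequency estimation; and the clinical
    anchors of the diagnosis (MDRD estimated glomerular filtration rate,
    urinary oxalate-to-creatinine ratio thresholds, pyridoxine-response
    criterion, and the adult PH1 diagnostic rule set). A synthetic-data
    module simulates pedigrees with planted haplotypes, alignments with
    planted per-column conservation, and diploid control cohorts, so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
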