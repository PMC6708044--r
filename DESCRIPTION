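Package: hifmapr
Title: High-Resolution QTL Fine-Mapping with Heterogeneous Inbred Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a quantitative trait locus (QTL) to a
    candidate gene the way wheat fine-mapping programs do it: Haley-Knott
    interval mapping on biparental populations, recombinant screening
    between flanking markers, progeny-test Mendelization of the locus with
    heterogeneous inbred families (HIFs), deduction of the candidate
    interval by recombination-breakpoint constraint intersection,
    haplotype-block analysis of SNP panels, diagnostic-marker allele
    classification, and allele-frequency and yield-component effect
    analyses. Includes a meiosis simulator for F2, selfed RIL and HIF
    populations so the whole inference chain can be exercised and validated
    on synthetic data, plus the published marker coordinates and diagnostic
    rules for the wheat 7AL spikelet-number locus (WAPO-A1) as worked
    reference inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    emmeans,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
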