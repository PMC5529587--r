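Package: mhcnest
Title: MHC Amplicon Genotyping and Functional-Allele Effects on Nestling Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying effects of MHC class I functional diversity on
    early survival and growth in pedigreed bird populations. Implements multi-step
    artifact filtering for tagged 454-style amplicon reads (including an exact
    multinomial coverage model for the per-sample read threshold), translation of
    MHC exon 3 alleles and collapse into functional alleles via peptide-binding-region
    z-descriptors, parental MHC similarity (proportion of functional alleles shared
    and unweighted UniFrac tree distances), multilocus microsatellite heterozygosity,
    and an iterative AICc-based model-selection procedure with relative variable
    importance and full model averaging. A synthetic-data module generates pedigreed
    populations with planted allele effects and noisy amplicon reads so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    picante,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
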