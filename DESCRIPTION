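Package: onilmap
Title: SNP-Array Design and Sex-Specific Linkage Maps for Nile Tilapia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested re-implementation of the analysis pipeline
    behind a high-density Nile tilapia (Oreochromis niloticus) genotyping array
    and its sex-specific genetic linkage maps: discovery-variant filtering
    (quality, depth, proximity-to-indel, allele-pair, genotype-quality masking,
    call completeness, minor allele frequency and an exact Hardy-Weinberg test),
    equidistant MAF-maximizing array selection with effect-prioritized picks,
    array genotype quality control with cluster-category classification,
    parentage assignment by opposing-homozygote exclusion, fixed physical-order
    sex-specific map estimation with Kosambi distances, Marey-map summaries,
    recombination-desert detection, and XY sex-locus mapping. A bundled
    synthetic-data generator produces founder cohorts and factorial full-sib
    families with sex-differentiated recombination so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
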