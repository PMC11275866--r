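Package: sinescout
Title: Mapping Recessive Retinal-Atrophy Loci and Calling Exonic SINE
    Insertions from Cohort Genotypes and Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of the discovery
    route used to map autosomal-recessive progressive retinal atrophy in
    dogs: quality control and runs-of-homozygosity mapping of SNP-array
    genotypes to a shared critical region, recessive-model filtering of
    annotated variant calls against within-cohort controls and a population
    panel, detection of mobile-element insertions from soft-clip clusters,
    localized depth elevation over the target-site duplication and
    discordant mate pairs, percent-identity classification of the inserted
    sequence against a repeat-consensus library, prediction of the
    protein-level consequence across transcript isoforms, and in-silico
    fragment-length genotyping with cohort segregation analysis. A seeded
    synthetic-data module generates every input format the pipeline
    consumes, with known ground truth, so each stage is verifiable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
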