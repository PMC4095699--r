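Package: impcna
Title: Copy-Number Landscape and Somatic Mutation Spectrum Analysis for
    Breast Carcinoma SNP-Array Cohorts
Version: 0.1.0
Authors@R:
    person("Nora", "Delattre", email = "nora.delattre@example.org",
           role = c("aut", "cre"))
Description: Ploidy-adaptive somatic copy-number alteration calling from
    allele-specific segmented SNP-array profiles, recurrent minimal-region
    discovery (the 25-SNP / >20% rule), loss-of-heterozygosity and
    breakpoint statistics, unsupervised genomic-subset discovery
    (Ward/Euclidean), somatic SNV filtering and mutation-spectrum
    summaries, copy-number/expression integration, and a synthetic cohort
    generator emulating the Sawtooth/8/16 and Firestorm/Amplifier tumour
    archetypes of invasive micropapillary breast carcinoma.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    withr
Config/testthat/edition: 3
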