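Package: cibmut
Title: Genome-Wide Profiling of Carbon-Ion-Beam Induced Mutations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis of carbon-ion-beam (CIB)
    mutagenesis resequencing experiments in selfing plants. Derives induced
    mutations by subtracting wild-type calls from mutant calls under GATK-style
    hard filters, characterises the single-base-substitution and InDel
    spectrum (Ti/Tv, twelve directional substitution types, InDel length
    histograms), assigns genomic-context and coding-effect categories with a
    strand-aware codon translation engine, scans windowed mutation frequencies
    for high-frequency (HF) regions and their SBS/InDel colocalization, and
    back-projects Mn mutation counts to M1 mutation rates under Mendelian
    selfing. Ships a synthetic-data module that generates toy genomes, gene
    models and planted mutation sets with truth tables so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
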