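Package: ftasseq
Title: Simulation and Anchored Fusion Calling for Terminator-Assisted
    Semi-Targeted RNA Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models fusion sequencing via terminator-assisted synthesis
    (FTAS-seq), a semi-targeted RNA-seq library chemistry in which a single
    gene-specific primer is extended in the presence of
    oligonucleotide-tethered dideoxynucleotide chain terminators, producing
    paired-end reads anchored at the target gene's 5' end with randomly
    terminated 3' ends. Provides a generative simulator of the library
    preparation (reverse transcription, terminator-assisted second-strand
    synthesis, nested indexing PCR, size selection, sequencing), adapter and
    quality trimming, and an anchored fusion caller that recovers
    3'-terminal fusion partners by chimeric split-read alignment, names
    fusion isoforms at exon/intron resolution, classifies reading frames,
    and applies replicate concordance and evidence-based confidence tiers.
    Ships a deterministic toy reference generator and cell-line-like sample
    presets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, GeneFusionDetection, Alignment,
    Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
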