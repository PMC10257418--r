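## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

toyRef <- function() {
  if (is.null(.fixtures$toy)) {
    dir <- file.path(tempdir(), "ftasseq-toy")
    dir.create(dir, showWarnings = FALSE)
    .fixtures$toy <- makeToyReference(seed = 1L,
                                     outPrefix = file.path(dir, "toy"))
  }
  .fixtures$toy
}

toyIndex <- function(cfg = CallerConfig()) {
  key <- paste0("idx-", cfg@minOverhang, "-", cfg@kmerSize)
  if (is.null(.fixtures[[key]])) {
    toy <- toyRef()
    .fixtures[[key]] <- fusionIndex(toy$genome, toy$models, cfg)
  }
  .fixtures[[key]]
}

## A small fusion-positive simulated library shared across caller tests.
toySim <- function() {
  if (is.null(.fixtures$sim)) {
    toy <- toyRef()
    pool <- samplePreset("nci-h660", toy$models, toy$genome)
    dir <- file.path(tempdir(), "ftasseq-sim")
    .fixtures$sim <- simulateLibrary(
      pool, LibraryConfig(depth = 20000L, seed = 11L), dir,
      nMolecules = 100000L)
  }
  .fixtures$sim
}

## Zero-sequencing-error read pair for a toy fusion with the given insert
## length (from the nested primer 5' end to the termination base).
cleanFusionPair <- function(isoform, insertLen, readLength = 150L,
                            models = toyRef()$models,
                            genome = toyRef()$genome) {
  seqF <- if (isoform == "WT") {
    transcriptSeq(canonicalModel(models, "TMPRSS2"), genome)
  } else {
    buildFusionTranscript(toyFusion(models, isoform), genome)
  }
  nStart <- regexpr(ftasseq:::FTAS_NESTED_PRIMER, seqF, fixed = TRUE)[1]
  insert <- substr(seqF, nStart, nStart + insertLen - 1L)
  pad <- strrep("A", readLength)
  r1 <- substr(paste0(insert, ftasseq:::FTAS_OTDDN_ADAPTER,
                      ftasseq:::FTAS_R1_POST_ADAPTER, pad), 1L, readLength)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(insert)))
  r2 <- substr(paste0(rc, ftasseq:::FTAS_R2_ADAPTER, pad), 1L, readLength)
  q <- strrep("?", readLength)
  list(r1 = r1, r2 = r2, q1 = q, q2 = q, insert = insert)
}
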