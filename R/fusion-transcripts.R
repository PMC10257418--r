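## Chimeric transcript construction, isoform naming and reading-frame
## classification.

## Genomic span of a gene including introns.
geneSpan <- function(m) {
  c(min(IRanges::start(m@exons)), max(IRanges::end(m@exons)))
}

## Transcript-orientation edges of exon/intron `idx`.
exonEdge3 <- function(m, idx) {
  if (m@strand == "+") IRanges::end(m@exons)[idx]
  else IRanges::start(m@exons)[idx]
}
exonEdge5 <- function(m, idx) {
  if (m@strand == "+") IRanges::start(m@exons)[idx]
  else IRanges::end(m@exons)[idx]
}

## Sense sequence of the retained part of intron `idx`: from the intron 5'
## edge to `pos` (fiveSide) or from `pos` to the intron 3' edge (threeSide).
intronRetained <- function(m, genome, idx, pos, fiveSide) {
  ir <- intronRanges(m)
  if (idx < 1L || idx > length(ir)) stop("no intron ", idx, " in ", m@transcriptId)
  s <- IRanges::start(ir)[idx]; e <- IRanges::end(ir)[idx]
  if (pos < s || pos > e)
    stop("position ", pos, " not inside intron ", idx, " of ", m@transcriptId)
  if (m@strand == "+") {
    if (fiveSide) senseSegment(genome, m@chrom, s, pos, "+")
    else senseSegment(genome, m@chrom, pos, e, "+")
  } else {
    if (fiveSide) senseSegment(genome, m@chrom, pos, e, "-")
    else senseSegment(genome, m@chrom, s, pos, "-")
  }
}

checkInGene <- function(m, pos) {
  sp <- geneSpan(m)
  if (pos < sp[1] || pos > sp[2])
    stop("breakpoint ", m@chrom, ":", pos, " falls outside gene ",
         m@symbol, " (gap between genes)")
}

#' Build the chimeric mRNA sequence of a fusion
#'
#' Concatenates the 5' gene's spliced transcript prefix through the 5'
#' breakpoint with the 3' segment from the 3' breakpoint to the transcript
#' end; no bases are gained or lost at the junction. Intronic breakpoints
#' retain the intron segment in genomic (sense) orientation;
#' `inverted_intronic` breakpoints retain the reverse complement of the
#' intron segment and end the transcript there.
#'
#' @param defn A [FusionDefinition-class].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Character scalar, the chimeric mRNA-sense sequence.
#' @examples
#' toy <- makeToyReference(seed = 1)
#' nchar(buildFusionTranscript(toyFusion(toy$models, "T1-E4"), toy$genome))
#' @export
buildFusionTranscript <- function(defn, genome) {
  paste0(fusionFivePrefix(defn, genome), fusionThreeSuffix(defn, genome))
}

fusionFivePrefix <- function(defn, genome) {
  m <- defn@fiveGene; bp <- defn@fiveBreakpoint
  checkInGene(m, bp@position)
  tx <- transcriptSeq(m, genome)
  switch(bp@feature,
    exon_boundary = {
      if (bp@position != exonEdge3(m, bp@index))
        stop("five_prime exon_boundary position does not coincide with the ",
             "3' edge of exon ", bp@index, " of ", m@symbol)
      substr(tx, 1L, genomicToTranscript(m, bp@position))
    },
    exonic_internal = ,
    noncoding = substr(tx, 1L, genomicToTranscript(m, bp@position)),
    intronic = {
      nExonBases <- sum(IRanges::width(m@exons)[seq_len(bp@index)])
      paste0(substr(tx, 1L, nExonBases),
             intronRetained(m, genome, bp@index, bp@position, fiveSide = TRUE))
    },
    inverted_intronic = stop("inverted_intronic is illegal on the five_prime side")
  )
}

fusionThreeSuffix <- function(defn, genome) {
  m <- defn@threeGene; bp <- defn@threeBreakpoint
  checkInGene(m, bp@position)
  tx <- transcriptSeq(m, genome)
  switch(bp@feature,
    exon_boundary = {
      if (bp@position != exonEdge5(m, bp@index))
        stop("three_prime exon_boundary position does not coincide with the ",
             "5' edge of exon ", bp@index, " of ", m@symbol)
      substr(tx, genomicToTranscript(m, bp@position), nchar(tx))
    },
    exonic_internal = ,
    noncoding = substr(tx, genomicToTranscript(m, bp@position), nchar(tx)),
    intronic = {
      downstream <- if (bp@index < exonCount(m)) {
        nBefore <- sum(IRanges::width(m@exons)[seq_len(bp@index)])
        substr(tx, nBefore + 1L, nchar(tx))
      } else ""
      paste0(intronRetained(m, genome, bp@index, bp@position, fiveSide = FALSE),
             downstream)
    },
    inverted_intronic =
      revComp(intronRetained(m, genome, bp@index, bp@position,
                             fiveSide = FALSE))
  )
}

#' Name a fusion isoform at exon/intron resolution
#'
#' Names follow `<5'code><5'unit>-<3'code><3'unit>`: gene codes are short
#' configurable abbreviations (see [defaultGeneCodes()]); units are arabic
#' exon numbers for exonic breakpoints and the Roman numeral of the
#' containing intron for intronic breakpoints (e.g. `T1-E4`, `T1-EIIIa`,
#' `T5-SVI`). When several intronic breakpoints share an intron, a
#' lowercase letter disambiguates them in order of increasing distance from
#' the preceding exon; inverted intronic segments render the plain Roman
#' numeral, the inversion being recorded in the call record.
#'
#' @param defn A [FusionDefinition-class] with annotated exon/intron
#'   indices on both breakpoints.
#' @param codes named character vector mapping gene symbols to codes;
#'   genes without a code are an error.
#' @param siblingPositions optional genomic positions (including this
#'   breakpoint's) of all intronic breakpoints observed in the same gene
#'   and intron, used to assign the disambiguating letter.
#' @return Character scalar isoform name.
#' @examples
#' toy <- makeToyReference(seed = 1)
#' nameIsoform(toyFusion(toy$models, "T1-E4"))
#' @export
nameIsoform <- function(defn, codes = defaultGeneCodes(),
                        siblingPositions = NULL) {
  codeOf <- function(m) {
    key <- toupper(m@symbol)
    if (!key %in% toupper(names(codes)))
      stop("no gene code configured for gene '", m@symbol, "'")
    codes[[which(toupper(names(codes)) == key)[1]]]
  }
  unitOf <- function(m, bp, siblings) {
    if (bp@feature %in% c("exon_boundary", "exonic_internal", "noncoding"))
      return(as.character(bp@index))
    rom <- romanIndex(bp@index)
    if (bp@feature == "inverted_intronic") return(rom)
    sibs <- sort(unique(c(bp@position, siblings)))
    if (m@strand == "-") sibs <- rev(sibs)
    paste0(rom, letters[match(bp@position, sibs)])
  }
  paste0(codeOf(defn@fiveGene),
         unitOf(defn@fiveGene, defn@fiveBreakpoint, NULL), "-",
         codeOf(defn@threeGene),
         unitOf(defn@threeGene, defn@threeBreakpoint, siblingPositions))
}

#' Classify the reading frame of a fusion
#'
#' A fusion is `in_frame` when both breakpoints lie within (or at the
#' boundaries of) annotated CDS and the codon phase immediately 5' of the
#' junction equals the phase immediately 3' of it; `out_of_frame` when both
#' sides are coding but the phases differ; and `unclear` when the 5' side
#' contributes no coding sequence (UTR-only breakpoints), the 3' breakpoint
#' is intronic, inverted or in a non-coding gene, or alternative annotated
#' transcripts of the 3' partner disagree on the phase.
#'
#' @param defn A [FusionDefinition-class].
#' @param models optional named list of [GeneModel-class]; all transcripts
#'   of the 3' gene found here are consulted, so alternative isoforms can
#'   render the frame unclear. Defaults to the models inside `defn`.
#' @return `"in_frame"`, `"out_of_frame"` or `"unclear"`.
#' @export
classifyReadingFrame <- function(defn, models = NULL) {
  m5 <- defn@fiveGene; bp5 <- defn@fiveBreakpoint
  if (bp5@feature %in% c("intronic", "noncoding") || !length(m5@cds))
    return("unclear")
  tc5 <- cdsTranscriptRange(m5)
  t5 <- genomicToTranscript(m5, bp5@position)
  L5 <- cdsBasesBefore(m5, t5 + 1L)       # CDS bases retained 5' of junction
  if (L5 == 0L || t5 > tc5$end) return("unclear")
  phase5 <- L5 %% 3L

  bp3 <- defn@threeBreakpoint
  if (bp3@feature %in% c("intronic", "inverted_intronic", "noncoding"))
    return("unclear")
  threeModels <- if (is.null(models)) list(defn@threeGene)
                 else geneModelsOf(models, defn@threeGene@geneId)
  threeModels <- Filter(function(m) length(m@cds) > 0L, threeModels)
  if (!length(threeModels)) return("unclear")

  verdicts <- character(0)
  for (m3 in threeModels) {
    t3 <- tryCatch(genomicToTranscript(m3, bp3@position),
                   error = function(e) NA_integer_)
    if (is.na(t3)) next
    tc3 <- cdsTranscriptRange(m3)
    if (t3 > tc3$end) { verdicts <- c(verdicts, "unclear"); next }
    required <- if (t3 <= tc3$start) (-(tc3$start - t3)) %% 3L
                else cdsBasesBefore(m3, t3) %% 3L
    verdicts <- c(verdicts,
                  if (phase5 == required) "in_frame" else "out_of_frame")
  }
  if (!length(verdicts)) return("unclear")
  if (all(verdicts == "in_frame")) return("in_frame")
  if (all(verdicts == "out_of_frame")) return("out_of_frame")
  "unclear"
}

#' Reference fusion definitions on the toy genome
#'
#' Convenience constructor for the fusion isoforms used by the bundled
#' sample presets and examples, specified by name: `"T1-E4"`, `"T2-E4"`,
#' `"T1-E5"`, `"T2-E5"` (TMPRSS2/ERG exon-exon junctions), `"T1-EIIIa"`
#' (partial ERG intron 3 followed by exon 4), `"T5-SVI"` (TMPRSS2 exon 5
#' fused to inverted SIM2 intron 6), `"T3-P2"` and `"T5-A2"` (in-frame
#' interchromosomal junctions).
#'
#' @param models toy gene models (see [makeToyReference()]).
#' @param name one of the isoform names above.
#' @return A [FusionDefinition-class].
#' @export
toyFusion <- function(models, name) {
  tm <- canonicalModel(models, "TMPRSS2")
  fiveAtExon <- function(idx)
    Breakpoint(tm@chrom, exonEdge3(tm, idx), "five_prime", "exon_boundary", idx)
  threeAtExon <- function(m, idx)
    Breakpoint(m@chrom, exonEdge5(m, idx), "three_prime", "exon_boundary", idx)
  erg <- canonicalModel(models, "ERG")
  switch(name,
    "T1-E4" = FusionDefinition(tm, fiveAtExon(1L), erg, threeAtExon(erg, 4L)),
    "T2-E4" = FusionDefinition(tm, fiveAtExon(2L), erg, threeAtExon(erg, 4L)),
    "T1-E5" = FusionDefinition(tm, fiveAtExon(1L), erg, threeAtExon(erg, 5L)),
    "T2-E5" = FusionDefinition(tm, fiveAtExon(2L), erg, threeAtExon(erg, 5L)),
    "T1-EIIIa" = {
      ir <- intronRanges(erg)
      pos <- IRanges::end(ir)[3L] - 79L   # retain the last 80 nt of intron 3
      FusionDefinition(tm, fiveAtExon(1L), erg,
        Breakpoint(erg@chrom, pos, "three_prime", "intronic", 3L))
    },
    "T5-SVI" = {
      sim2 <- canonicalModel(models, "SIM2")
      ir <- intronRanges(sim2)
      pos <- IRanges::start(ir)[6L] + 19L
      FusionDefinition(tm, fiveAtExon(5L), sim2,
        Breakpoint(sim2@chrom, pos, "three_prime", "inverted_intronic", 6L,
                   strandOfRetained = "-"))
    },
    "T3-P2" = {
      p <- canonicalModel(models, "PPP3CA")
      FusionDefinition(tm, fiveAtExon(3L), p, threeAtExon(p, 2L))
    },
    "T5-A2" = {
      a <- canonicalModel(models, "AMACR")
      FusionDefinition(tm, fiveAtExon(5L), a, threeAtExon(a, 2L))
    },
    stop("unknown toy fusion '", name, "'")
  )
}
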