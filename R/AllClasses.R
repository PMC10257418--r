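## S4 classes for the central domain objects.

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Gene model: one transcript of one gene
#'
#' A `GeneModel` holds one transcript of a gene: its ordered exons (genomic
#' coordinates, 1-based inclusive), strand, and an optional coding region.
#' Exons are stored in transcript orientation, i.e. element 1 is the 5'-most
#' exon of the mRNA; for minus-strand genes that is the exon with the
#' largest genomic coordinates. Exon and intron numbering used throughout
#' (isoform names such as "T1-E4", intron Roman numerals) is 1-based in
#' this orientation.
#'
#' @slot geneId gene identifier (GTF `gene_id`).
#' @slot symbol gene symbol used for isoform-name gene codes.
#' @slot chrom reference sequence name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exons in transcript orientation.
#' @slot cds [IRanges::IRanges] of coding intervals in transcript
#'   orientation; zero-length for non-coding transcripts. A complete CDS has
#'   total length divisible by 3.
#' @slot transcriptId transcript identifier.
#'
#' @seealso [loadAnnotation()], [transcriptSeq()], [exonCount()]
#' @export
setClass("GeneModel", slots = c(
  geneId = "character", symbol = "character", chrom = "character",
  strand = "character", exons = "IRanges", cds = "IRanges",
  transcriptId = "character"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    s <- IRanges::start(ex)
    ordered <- if (object@strand == "+") all(diff(s) > 0) else all(diff(s) < 0)
    if (!ordered)
      msg <- c(msg, "exons must be sorted in transcript orientation")
    gs <- sort(IRanges::start(ex)); ge <- sort(IRanges::end(ex))
    if (any(gs[-1] <= ge[-length(ge)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (length(object@cds)) {
    within <- vapply(seq_along(object@cds), function(i) {
      any(IRanges::start(object@cds)[i] >= IRanges::start(ex) &
          IRanges::end(object@cds)[i] <= IRanges::end(ex))
    }, logical(1))
    if (!all(within)) msg <- c(msg, "every CDS interval must lie in an exon")
    if (sum(IRanges::width(object@cds)) %% 3L != 0L)
      msg <- c(msg, "total CDS length must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId,symbol,chrom,strand,transcriptId character scalars.
#' @param exons matrix-like or IRanges of exon (start, end) genomic
#'   coordinates; any order, sorted into transcript orientation.
#' @param cds optional CDS intervals, same conventions as `exons`.
#' @return A [GeneModel-class] object.
#' @examples
#' gm <- GeneModel("g1", "G1", "chr1", "+", cbind(c(101, 301), c(200, 400)))
#' exonCount(gm)
#' @export
GeneModel <- function(geneId, symbol, chrom, strand, exons, cds = NULL,
                      transcriptId = paste0(geneId, ".t1")) {
  toIR <- function(x) {
    if (is.null(x)) return(IRanges::IRanges())
    if (is(x, "IRanges")) return(x)
    x <- as.matrix(x)
    IRanges::IRanges(start = as.integer(x[, 1]), end = as.integer(x[, 2]))
  }
  ex <- toIR(exons)
  ord <- order(IRanges::start(ex), decreasing = (strand == "-"))
  ex <- ex[ord]
  cd <- toIR(cds)
  if (length(cd)) cd <- cd[order(IRanges::start(cd), decreasing = (strand == "-"))]
  new("GeneModel", geneId = geneId, symbol = symbol, chrom = chrom,
      strand = strand, exons = ex, cds = cd, transcriptId = transcriptId)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s) %s:%d-%d(%s), %d exon(s)%s\n",
              object@transcriptId, object@symbol, object@chrom,
              min(IRanges::start(object@exons)),
              max(IRanges::end(object@exons)),
              object@strand, length(object@exons),
              if (length(object@cds)) sprintf(", CDS %d nt",
                sum(IRanges::width(object@cds))) else ", non-coding"))
})

#' Fusion breakpoint
#'
#' One side of a fusion junction. `position` is the genomic coordinate
#' (1-based) of the last retained base of the 5' segment
#' (`side = "five_prime"`) or the first retained base of the 3' segment
#' (`side = "three_prime"`). `feature` records the junction structure:
#' breakpoints at annotated exon edges (`"exon_boundary"`), inside exons
#' (`"exonic_internal"`), inside introns (`"intronic"`), retained inverted
#' intron sequence (`"inverted_intronic"`, legal only on the 3' side), or in
#' non-coding transcripts (`"noncoding"`). `index` is the exon (or, for
#' intronic features, intron) number in transcript orientation.
#'
#' @export
setClass("Breakpoint", slots = c(
  chrom = "character", position = "integer", side = "character",
  feature = "character", index = "integer", strandOfRetained = "character"))

setValidity("Breakpoint", function(object) {
  msg <- character(0)
  if (!object@side %in% c("five_prime", "three_prime"))
    msg <- c(msg, "side must be 'five_prime' or 'three_prime'")
  feats <- c("exon_boundary", "exonic_internal", "intronic",
             "inverted_intronic", "noncoding")
  if (!object@feature %in% feats)
    msg <- c(msg, paste("feature must be one of:", paste(feats, collapse = ", ")))
  if (object@feature == "inverted_intronic" && object@side == "five_prime")
    msg <- c(msg, "inverted_intronic is only legal on the three_prime side")
  if (length(msg)) msg else TRUE
})

#' @rdname Breakpoint-class
#' @param chrom,side,feature,strandOfRetained character scalars.
#' @param position,index integer scalars.
#' @export
Breakpoint <- function(chrom, position, side, feature, index,
                       strandOfRetained = "+") {
  new("Breakpoint", chrom = chrom, position = as.integer(position),
      side = side, feature = feature, index = as.integer(index),
      strandOfRetained = strandOfRetained)
}

setMethod("show", "Breakpoint", function(object) {
  cat(sprintf("Breakpoint %s:%d [%s, %s %d]\n", object@chrom,
              object@position, object@side, object@feature, object@index))
})

#' Fusion definition
#'
#' A fusion transcript defined by a 5' gene + breakpoint and a 3' gene +
#' breakpoint. The chimeric mRNA is the 5' transcript prefix through the 5'
#' breakpoint concatenated with the 3' segment from the 3' breakpoint
#' onward; no bases are gained or lost at the junction.
#'
#' @seealso [buildFusionTranscript()], [nameIsoform()],
#'   [classifyReadingFrame()]
#' @export
setClass("FusionDefinition", slots = c(
  fiveGene = "GeneModel", fiveBreakpoint = "Breakpoint",
  threeGene = "GeneModel", threeBreakpoint = "Breakpoint"))

setValidity("FusionDefinition", function(object) {
  msg <- character(0)
  if (object@fiveBreakpoint@side != "five_prime")
    msg <- c(msg, "fiveBreakpoint must have side 'five_prime'")
  if (object@threeBreakpoint@side != "three_prime")
    msg <- c(msg, "threeBreakpoint must have side 'three_prime'")
  if (length(msg)) msg else TRUE
})

#' @rdname FusionDefinition-class
#' @param fiveGene,threeGene [GeneModel-class] objects.
#' @param fiveBreakpoint,threeBreakpoint [Breakpoint-class] objects.
#' @export
FusionDefinition <- function(fiveGene, fiveBreakpoint, threeGene,
                             threeBreakpoint) {
  new("FusionDefinition", fiveGene = fiveGene, fiveBreakpoint = fiveBreakpoint,
      threeGene = threeGene, threeBreakpoint = threeBreakpoint)
}

setMethod("show", "FusionDefinition", function(object) {
  cat(sprintf("FusionDefinition %s(%s:%d) -> %s(%s:%d)\n",
              object@fiveGene@symbol, object@fiveBreakpoint@chrom,
              object@fiveBreakpoint@position, object@threeGene@symbol,
              object@threeBreakpoint@chrom, object@threeBreakpoint@position))
})

#' Nucleotide/terminator reaction mix
#'
#' Concentrations (micromolar) of the four deoxynucleotides and of the two
#' oligonucleotide-tethered dideoxynucleotide (OTDDN) chain terminators
#' (ddC and ddU analogues). Incorporation competition is modelled as
#' concentration-proportional with equal efficiency, so the per-incorporation
#' termination probability in each pyrimidine channel is
#' `terminator / (terminator + dNTP)`. Defaults are the reaction-mix values
#' of the chemistry (1 uM dATP/dGTP, 0.9 uM dTTP/dCTP, 0.1 uM each OTDDN),
#' giving a termination probability of 0.1 per incorporated pyrimidine.
#'
#' @seealso [terminationProbs()], [extendWithTerminators()]
#' @export
setClass("NucleotideMix", slots = c(
  dATP = "numeric", dGTP = "numeric", dCTP = "numeric", dTTP = "numeric",
  ddC_ON = "numeric", ddU_ON = "numeric"))

setValidity("NucleotideMix", function(object) {
  v <- c(object@dATP, object@dGTP, object@dCTP, object@dTTP,
         object@ddC_ON, object@ddU_ON)
  msg <- character(0)
  if (any(v < 0)) msg <- c(msg, "concentrations must be non-negative")
  if (object@dCTP + object@ddC_ON <= 0)
    msg <- c(msg, "dCTP + ddC_ON must be positive")
  if (object@dTTP + object@ddU_ON <= 0)
    msg <- c(msg, "dTTP + ddU_ON must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname NucleotideMix-class
#' @param dATP,dGTP,dCTP,dTTP,ddC_ON,ddU_ON concentrations in uM.
#' @examples
#' terminationProbs(NucleotideMix())
#' @export
NucleotideMix <- function(dATP = 1, dGTP = 1, dCTP = 0.9, dTTP = 0.9,
                          ddC_ON = 0.1, ddU_ON = 0.1) {
  new("NucleotideMix", dATP = dATP, dGTP = dGTP, dCTP = dCTP, dTTP = dTTP,
      ddC_ON = ddC_ON, ddU_ON = ddU_ON)
}

#' Termination probabilities of a nucleotide mix
#'
#' @param mix A [NucleotideMix-class].
#' @return Named numeric `c(C = , T = )`: probability that an incorporated
#'   C (resp. T) is a chain-terminating OTDDN.
#' @export
terminationProbs <- function(mix) {
  c(C = mix@ddC_ON / (mix@ddC_ON + mix@dCTP),
    T = mix@ddU_ON / (mix@ddU_ON + mix@dTTP))
}

setMethod("show", "NucleotideMix", function(object) {
  p <- terminationProbs(object)
  cat(sprintf(paste0("NucleotideMix (uM): dATP=%g dGTP=%g dCTP=%g dTTP=%g ",
                     "ddC_ON=%g ddU_ON=%g\n  p_term: C=%.4f T=%.4f\n"),
              object@dATP, object@dGTP, object@dCTP, object@dTTP,
              object@ddC_ON, object@ddU_ON, p["C"], p["T"]))
})

#' Library preparation configuration
#'
#' All tunable parameters of the simulated FTAS-seq library preparation.
#' Defaults follow the published protocol: 15 linear extension cycles with
#' the terminator mix, 20 nested indexing PCR cycles, 2 x 150 bp paired-end
#' reads, duplicate technical replicates.
#'
#' @slot outerPrimer anchor-gene-specific primer driving terminator-assisted
#'   second-strand synthesis.
#' @slot nestedPrimer inner primer (3' portion of the indexing i5 primer)
#'   that re-anchors surviving molecules; every on-target R1 begins with it.
#' @slot otddnAdapter adapter tethered to the terminating base.
#' @slot mix a [NucleotideMix-class].
#' @slot extensionCycles linear extension cycles (one nascent strand per
#'   template per cycle).
#' @slot pcrCycles,pcrEfficiency indexing PCR cycles and per-cycle success
#'   probability of the Galton-Watson duplication process.
#' @slot sizeWindow `c(min, max)` insert size retained by size selection.
#' @slot readLength read length in nt.
#' @slot substitutionRate iid per-base substitution error rate.
#' @slot indelRate per-base indel rate (0 by default; substitution-only).
#' @slot degradationRate per-phosphodiester-bond fragmentation probability
#'   of the input RNA (0 models intact cell-line RNA).
#' @slot randomPrimingFraction fraction of reverse-transcription events
#'   primed at a uniform internal position rather than at the fragment 3'
#'   end (oligo-dT).
#' @slot depth sequenced read pairs per replicate.
#' @slot replicates number of technical replicates.
#' @slot seed master seed; per-replicate and per-stage sub-seeds are derived
#'   from it.
#' @export
setClass("LibraryConfig", slots = c(
  outerPrimer = "character", nestedPrimer = "character",
  otddnAdapter = "character", mix = "NucleotideMix",
  extensionCycles = "integer", pcrCycles = "integer",
  pcrEfficiency = "numeric", sizeWindow = "integer", readLength = "integer",
  substitutionRate = "numeric", indelRate = "numeric",
  degradationRate = "numeric", randomPrimingFraction = "numeric",
  depth = "integer", replicates = "integer", seed = "integer"))

setValidity("LibraryConfig", function(object) {
  msg <- character(0)
  if (object@readLength <= 0L) msg <- c(msg, "readLength must be positive")
  if (object@pcrEfficiency < 0 || object@pcrEfficiency > 1)
    msg <- c(msg, "pcrEfficiency must lie in [0, 1]")
  if (length(object@sizeWindow) != 2L ||
      object@sizeWindow[1] > object@sizeWindow[2])
    msg <- c(msg, "sizeWindow must be c(min, max) with min <= max")
  if (object@sizeWindow[1] < nchar(object@nestedPrimer) + 10L)
    msg <- c(msg, "sizeWindow minimum must cover the nested primer plus a minimum overhang")
  if (length(msg)) msg else TRUE
})

#' @rdname LibraryConfig-class
#' @param outerPrimer,nestedPrimer,otddnAdapter,mix,extensionCycles,pcrCycles
#'   see slots.
#' @param pcrEfficiency,sizeWindow,readLength,substitutionRate,indelRate see
#'   slots.
#' @param degradationRate,randomPrimingFraction,depth,replicates,seed see
#'   slots.
#' @export
LibraryConfig <- function(outerPrimer = FTAS_OUTER_PRIMER,
                          nestedPrimer = FTAS_NESTED_PRIMER,
                          otddnAdapter = FTAS_OTDDN_ADAPTER,
                          mix = NucleotideMix(),
                          extensionCycles = 15L, pcrCycles = 20L,
                          pcrEfficiency = 0.9, sizeWindow = c(50L, 700L),
                          readLength = 150L, substitutionRate = 0.001,
                          indelRate = 0, degradationRate = 0,
                          randomPrimingFraction = 0.5,
                          depth = 100000L, replicates = 2L, seed = 1L) {
  new("LibraryConfig", outerPrimer = outerPrimer, nestedPrimer = nestedPrimer,
      otddnAdapter = otddnAdapter, mix = mix,
      extensionCycles = as.integer(extensionCycles),
      pcrCycles = as.integer(pcrCycles), pcrEfficiency = pcrEfficiency,
      sizeWindow = as.integer(sizeWindow), readLength = as.integer(readLength),
      substitutionRate = substitutionRate, indelRate = indelRate,
      degradationRate = degradationRate,
      randomPrimingFraction = randomPrimingFraction,
      depth = as.integer(depth), replicates = as.integer(replicates),
      seed = as.integer(seed))
}

setMethod("show", "LibraryConfig", function(object) {
  cat(sprintf(paste0("LibraryConfig: %d extension + %d PCR cycles ",
                     "(eff %.2f), insert %d-%d nt, 2 x %d bp, depth %d x %d ",
                     "replicate(s), sub rate %.4g, seed %d\n"),
              object@extensionCycles, object@pcrCycles, object@pcrEfficiency,
              object@sizeWindow[1], object@sizeWindow[2], object@readLength,
              object@depth, object@replicates, object@substitutionRate,
              object@seed))
})

#' Read trimming configuration
#'
#' Adapter/quality trimming parameters: right-side adapter k-mer trimming
#' (seed length `adapterKmer` shortening to `adapterMinKmer` at the read
#' end, `adapterMaxMismatch` mismatches allowed), right-side quality
#' trimming below `qtrimThreshold`, pair-equalising trim when one mate is
#' adapter-trimmed, and pair discard below `minLength` or above `maxN`
#' ambiguous bases.
#'
#' @export
setClass("TrimConfig", slots = c(
  minLength = "integer", qtrimThreshold = "integer", maxN = "integer",
  adapterKmer = "integer", adapterMinKmer = "integer",
  adapterMaxMismatch = "integer", adapters = "character"))

setValidity("TrimConfig", function(object) {
  msg <- character(0)
  if (object@minLength <= 0L) msg <- c(msg, "minLength must be positive")
  if (object@qtrimThreshold < 0L || object@maxN < 0L)
    msg <- c(msg, "thresholds must be non-negative")
  if (object@adapterMinKmer > object@adapterKmer)
    msg <- c(msg, "adapterMinKmer must not exceed adapterKmer")
  if (length(msg)) msg else TRUE
})

#' @rdname TrimConfig-class
#' @param minLength,qtrimThreshold,maxN,adapterKmer,adapterMinKmer integer
#'   scalars.
#' @param adapterMaxMismatch mismatches tolerated in an adapter k-mer match.
#' @param adapters adapter sequences searched on the right of each read.
#' @export
TrimConfig <- function(minLength = 50L, qtrimThreshold = 15L, maxN = 1L,
                       adapterKmer = 23L, adapterMinKmer = 11L,
                       adapterMaxMismatch = 1L,
                       adapters = c(FTAS_OTDDN_ADAPTER, FTAS_R2_ADAPTER)) {
  new("TrimConfig", minLength = as.integer(minLength),
      qtrimThreshold = as.integer(qtrimThreshold), maxN = as.integer(maxN),
      adapterKmer = as.integer(adapterKmer),
      adapterMinKmer = as.integer(adapterMinKmer),
      adapterMaxMismatch = as.integer(adapterMaxMismatch),
      adapters = adapters)
}

setMethod("show", "TrimConfig", function(object) {
  cat(sprintf(paste0("TrimConfig: minLength=%d qtrim(right)<Q%d maxN=%d ",
                     "adapter k=%d mink=%d hdist=%d, %d adapter(s)\n"),
              object@minLength, object@qtrimThreshold, object@maxN,
              object@adapterKmer, object@adapterMinKmer,
              object@adapterMaxMismatch, length(object@adapters)))
})

#' Fusion caller configuration
#'
#' Parameters of the anchored fusion caller. A chimeric alignment is
#' accepted only when both segments are at least `minSegment` nt and both
#' junction overhangs at least `minOverhang` nt; junctions within
#' `junctionMergeWindow` nt are merged into one call reported at the modal
#' coordinate. Confidence tiers are keyed to supporting evidence: high
#' requires `highMinFragments` unique fragments and `highMinTerminations`
#' distinct termination coordinates, medium requires `mediumMinFragments`
#' fragments, anything else is low.
#'
#' @export
setClass("CallerConfig", slots = c(
  anchorGene = "character", nestedPrimer = "character",
  anchorMaxMismatch = "integer", kmerSize = "integer", minSegment = "integer",
  minOverhang = "integer", junctionMergeWindow = "integer",
  minSplitReads = "integer", highMinFragments = "integer",
  highMinTerminations = "integer", mediumMinFragments = "integer",
  requireBothReplicates = "logical"))

setValidity("CallerConfig", function(object) {
  msg <- character(0)
  if (object@minOverhang < 1L) msg <- c(msg, "minOverhang must be >= 1")
  if (object@kmerSize < 8L) msg <- c(msg, "kmerSize must be >= 8")
  if (object@kmerSize > object@minSegment + 5L)
    msg <- c(msg, "kmerSize must not exceed minSegment + 5 (seeds must fit in the minimum segment)")
  if (length(msg)) msg else TRUE
})

#' @rdname CallerConfig-class
#' @param anchorGene gene id of the anchor (5') gene.
#' @param nestedPrimer primer prefix every on-target R1 must start with.
#' @param anchorMaxMismatch,kmerSize,minSegment,minOverhang integer scalars.
#' @param junctionMergeWindow,minSplitReads,highMinFragments integer scalars.
#' @param highMinTerminations,mediumMinFragments integer scalars.
#' @param requireBothReplicates drop calls lacking support in both
#'   technical replicates.
#' @export
CallerConfig <- function(anchorGene = "TMPRSS2",
                         nestedPrimer = FTAS_NESTED_PRIMER,
                         anchorMaxMismatch = 1L, kmerSize = 15L,
                         minSegment = 10L, minOverhang = 10L,
                         junctionMergeWindow = 3L, minSplitReads = 1L,
                         highMinFragments = 5L, highMinTerminations = 2L,
                         mediumMinFragments = 2L,
                         requireBothReplicates = TRUE) {
  new("CallerConfig", anchorGene = anchorGene, nestedPrimer = nestedPrimer,
      anchorMaxMismatch = as.integer(anchorMaxMismatch),
      kmerSize = as.integer(kmerSize), minSegment = as.integer(minSegment),
      minOverhang = as.integer(minOverhang),
      junctionMergeWindow = as.integer(junctionMergeWindow),
      minSplitReads = as.integer(minSplitReads),
      highMinFragments = as.integer(highMinFragments),
      highMinTerminations = as.integer(highMinTerminations),
      mediumMinFragments = as.integer(mediumMinFragments),
      requireBothReplicates = requireBothReplicates)
}

setMethod("show", "CallerConfig", function(object) {
  cat(sprintf(paste0("CallerConfig: anchor=%s k=%d minSegment=%d ",
                     "minOverhang=%d mergeWindow=%d tiers(high>=%d frags & ",
                     ">=%d terms; medium>=%d), bothReplicates=%s\n"),
              object@anchorGene, object@kmerSize, object@minSegment,
              object@minOverhang, object@junctionMergeWindow,
              object@highMinFragments, object@highMinTerminations,
              object@mediumMinFragments, object@requireBothReplicates))
})
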