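## Gene-model accessors, coordinate arithmetic, and annotation I/O.

#' @describeIn GeneModel number of exons.
#' @param x,object A `GeneModel`.
#' @export
exonCount <- function(x) length(x@exons)

#' Transcript length in nt (sum of exon widths)
#' @param x A [GeneModel-class].
#' @export
transcriptLength <- function(x) sum(IRanges::width(x@exons))

#' Intron ranges of a gene model
#'
#' @param x A [GeneModel-class].
#' @return [IRanges::IRanges] of introns in transcript orientation (intron
#'   `i` separates exon `i` from exon `i + 1`); genomic coordinates.
#' @export
intronRanges <- function(x) {
  n <- exonCount(x)
  if (n < 2L) return(IRanges::IRanges())
  ex <- x@exons
  if (x@strand == "+") {
    IRanges::IRanges(start = IRanges::end(ex)[-n] + 1L,
                     end = IRanges::start(ex)[-1L] - 1L)
  } else {
    IRanges::IRanges(start = IRanges::end(ex)[-1L] + 1L,
                     end = IRanges::start(ex)[-n] - 1L)
  }
}

#' Map a genomic position to a transcript coordinate
#'
#' @param x A [GeneModel-class].
#' @param gpos genomic position(s), 1-based; must fall inside an exon.
#' @return 1-based transcript coordinate(s) (position within the spliced
#'   mRNA, 5' to 3').
#' @export
genomicToTranscript <- function(x, gpos) {
  ex <- x@exons
  starts <- IRanges::start(ex); ends <- IRanges::end(ex)
  cumw <- cumsum(IRanges::width(ex))
  offs <- c(0L, cumw[-length(cumw)])
  vapply(gpos, function(g) {
    i <- which(g >= starts & g <= ends)
    if (length(i) != 1L)
      stop("position ", g, " is not exonic in ", x@transcriptId)
    if (x@strand == "+") offs[i] + (g - starts[i] + 1L)
    else offs[i] + (ends[i] - g + 1L)
  }, integer(1))
}

#' Map a transcript coordinate to a genomic position
#'
#' Inverse of [genomicToTranscript()].
#' @param x A [GeneModel-class].
#' @param tpos 1-based transcript coordinate(s).
#' @export
transcriptToGenomic <- function(x, tpos) {
  ex <- x@exons
  cumw <- cumsum(IRanges::width(ex))
  offs <- c(0L, cumw[-length(cumw)])
  vapply(tpos, function(t) {
    if (t < 1L || t > transcriptLength(x))
      stop("transcript coordinate ", t, " outside ", x@transcriptId)
    i <- findInterval(t - 1L, cumw) + 1L
    d <- t - offs[i]
    if (x@strand == "+") IRanges::start(ex)[i] + d - 1L
    else IRanges::end(ex)[i] - d + 1L
  }, integer(1))
}

#' Spliced transcript sequence (mRNA sense)
#'
#' @param x A [GeneModel-class].
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Character scalar: the spliced mRNA-sense sequence.
#' @export
transcriptSeq <- function(x, genome) {
  chromSeq(genome, x@chrom)  # bounds check
  pieces <- vapply(seq_along(x@exons), function(i) {
    s <- IRanges::start(x@exons)[i]; e <- IRanges::end(x@exons)[i]
    seg <- as.character(subseq(genome[[x@chrom]], s, e))
    if (x@strand == "-") revComp(seg) else seg
  }, character(1))
  paste(pieces, collapse = "")
}

## Genomic segment in the gene's sense orientation (start <= end genomic).
senseSegment <- function(genome, chrom, start, end, strand) {
  seg <- as.character(subseq(genome[[chrom]], start, end))
  if (strand == "-") revComp(seg) else seg
}

chromSeq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("reference sequence '", chrom, "' not present in genome")
  genome[[chrom]]
}

#' Number of CDS bases at transcript positions strictly before `tpos`
#'
#' Used for reading-frame phase arithmetic. Returns `NA` when the model has
#' no CDS.
#' @param x A [GeneModel-class].
#' @param tpos 1-based transcript coordinate.
#' @keywords internal
cdsBasesBefore <- function(x, tpos) {
  if (!length(x@cds)) return(NA_integer_)
  tc <- cdsTranscriptRange(x)
  sum(pmax(0L, pmin(tpos - 1L, tc[["end"]]) - tc[["start"]] + 1L))
}

## CDS as (start, end) transcript coordinates; the CDS is contiguous in
## transcript space so a single interval suffices.
cdsTranscriptRange <- function(x) {
  stopifnot(length(x@cds) > 0L)
  gstarts <- IRanges::start(x@cds); gends <- IRanges::end(x@cds)
  tpos <- c(genomicToTranscript(x, gstarts), genomicToTranscript(x, gends))
  list(start = min(tpos), end = max(tpos))
}

#' Load gene models from a GTF annotation and reference FASTA
#'
#' Parses `exon` and `CDS` features grouped by `transcript_id` into
#' [GeneModel-class] objects. Exon order follows the `exon_number`
#' attribute when present, otherwise genomic coordinates in transcript
#' orientation (so reverse-strand genes get exon 1 at the genomic right
#' end). Records referencing sequences absent from the FASTA, or exons
#' outside sequence bounds, are hard errors naming the offending record.
#'
#' @param annotationFile path to a GTF file.
#' @param genomeFile path to the reference FASTA (or a
#'   [Biostrings::DNAStringSet]).
#' @return Named list of [GeneModel-class] objects (names = transcript ids),
#'   in file order; the first transcript of each gene is treated as its
#'   canonical transcript downstream.
#' @export
loadAnnotation <- function(annotationFile, genomeFile) {
  genome <- if (is(genomeFile, "DNAStringSet")) genomeFile else
    readDNAStringSet(genomeFile)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(annotationFile, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  txIds <- unique(md$transcript_id)
  models <- lapply(txIds, function(tx) {
    sel <- md$transcript_id == tx
    sub <- gr[sel]; smd <- md[sel, , drop = FALSE]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    strand <- as.character(BiocGenerics::strand(sub))[1]
    if (!chrom %in% names(genome))
      stop("transcript ", tx, " references missing sequence '", chrom, "'")
    isExon <- smd$type == "exon"
    exGr <- sub[isExon]
    if (any(BiocGenerics::end(exGr) > length(genome[[chrom]])) ||
        any(BiocGenerics::start(exGr) < 1L))
      stop("exon of transcript ", tx, " outside bounds of '", chrom, "'")
    exNum <- smd$exon_number[isExon]
    ord <- if (!is.null(exNum) && !anyNA(exNum)) order(as.integer(exNum))
           else order(BiocGenerics::start(exGr), decreasing = (strand == "-"))
    exons <- IRanges::IRanges(BiocGenerics::start(exGr)[ord],
                              BiocGenerics::end(exGr)[ord])
    cdsGr <- sub[!isExon]
    cds <- if (length(cdsGr))
      IRanges::IRanges(BiocGenerics::start(cdsGr), BiocGenerics::end(cdsGr))
    else NULL
    geneId <- smd$gene_id[1] %||% tx
    sym <- if (!is.null(smd$gene_name)) smd$gene_name[1] else geneId
    GeneModel(geneId = geneId, symbol = sym %||% geneId, chrom = chrom,
              strand = strand, exons = exons, cds = cds, transcriptId = tx)
  })
  names(models) <- txIds
  models
}

#' Canonical model of a gene
#'
#' The first transcript listed for a gene id (or symbol) is its canonical
#' transcript; isoform naming and exon numbering use it.
#' @param models named list of [GeneModel-class] (see [loadAnnotation()]).
#' @param gene gene id or symbol.
#' @export
canonicalModel <- function(models, gene) {
  hit <- Filter(function(m) m@geneId == gene || m@symbol == gene, models)
  if (!length(hit)) stop("no gene model for '", gene, "'")
  hit[[1]]
}

#' All models of a gene (alternative transcripts)
#' @inheritParams canonicalModel
#' @export
geneModelsOf <- function(models, gene) {
  hit <- Filter(function(m) m@geneId == gene || m@symbol == gene, models)
  if (!length(hit)) stop("no gene model for '", gene, "'")
  hit
}

## Emit gene models as GTF text lines (deterministic, byte-stable).
gtfLines <- function(models) {
  unlist(lapply(models, function(m) {
    attrsBase <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                         m@geneId, m@transcriptId, m@symbol)
    ex <- m@exons
    exLines <- vapply(seq_along(ex), function(i) {
      sprintf("%s\tftasseq\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
              m@chrom, IRanges::start(ex)[i], IRanges::end(ex)[i], m@strand,
              attrsBase, i)
    }, character(1))
    cdLines <- if (length(m@cds)) {
      vapply(seq_along(m@cds), function(i) {
        sprintf("%s\tftasseq\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                m@chrom, IRanges::start(m@cds)[i], IRanges::end(m@cds)[i],
                m@strand, attrsBase)
      }, character(1))
    } else character(0)
    c(exLines, cdLines)
  }), use.names = FALSE)
}
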