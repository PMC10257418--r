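## Exact k-mer index over reference sequences, the seeding structure of the
## split mapper (in place of a full spliced aligner: the caller only ever
## anchors one side of each read, so exact seeds plus base-level extension
## suffice).

#' FusionIndex: seeding and annotation context of the anchored caller
#'
#' Holds everything [splitMapPair()] needs: the k-mer seed table over the
#' genome (both strands) and the canonical spliced transcripts (sense
#' strand, so exon-exon joins within one gene chain as a single locus), the
#' reference sequences themselves, the gene models, the caller
#' configuration, and the precomputed anchor-transcript context (expected
#' wild-type read content downstream of the nested primer).
#'
#' @seealso [fusionIndex()], [buildKmerIndex()]
#' @export
setClass("FusionIndex", slots = c(
  kmers = "ANY", k = "integer", refSeqs = "character", refLen = "integer",
  models = "list", cfg = "CallerConfig", anchorModel = "GeneModel",
  anchorTx = "character", nestedT0 = "integer", codes = "character"))

setMethod("show", "FusionIndex", function(object) {
  cat(sprintf(paste0("FusionIndex: %d refs (%d genome strands + %d ",
                     "transcripts), k=%d, %d seeds, anchor=%s\n"),
              length(object@refSeqs),
              sum(!startsWith(names(object@refSeqs), "tx:")),
              sum(startsWith(names(object@refSeqs), "tx:")), object@k,
              nrow(object@kmers), object@anchorModel@symbol))
})

#' Build an exact k-mer position table
#'
#' Indexes every k-mer of every sequence; with `bothStrands = TRUE` the
#' reverse complement of each sequence is indexed too (strand `"-"`, with
#' positions relative to the reverse-complemented sequence). Deterministic;
#' duplicate sequence names are an error.
#'
#' @param seqs named character vector, [Biostrings::DNAStringSet], or FASTA
#'   path.
#' @param k k-mer length (>= 8).
#' @param bothStrands index the reverse complement as well.
#' @return A keyed [data.table::data.table] with columns `kmer`, `ref`,
#'   `pos`, `strand`.
#' @examples
#' idx <- buildKmerIndex(c(s1 = strrep("ACGT", 25)), k = 15)
#' nrow(idx)  # 86 positions per strand
#' @export
buildKmerIndex <- function(seqs, k = 15L, bothStrands = TRUE) {
  if (k < 8L) stop("k must be >= 8")
  if (is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.character(seqs) && is.null(names(seqs)) && length(seqs) == 1L &&
      file.exists(seqs))
    seqs <- setNames(as.character(readDNAStringSet(seqs)),
                     names(readDNAStringSet(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  one <- function(s, nm, strand) {
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table(kmer = substring(s, starts, starts + k - 1L), ref = nm,
               pos = starts, strand = strand)
  }
  parts <- lapply(names(seqs), function(nm) {
    fwd <- one(seqs[[nm]], nm, "+")
    if (!bothStrands) fwd
    else rbindlist(list(fwd, one(revComp(seqs[[nm]]), nm, "-")))
  })
  dt <- rbindlist(parts)
  setkey(dt, kmer)
  dt
}

#' Build the caller context for a reference
#'
#' @param genome named [Biostrings::DNAStringSet] (or FASTA path).
#' @param models named list of [GeneModel-class] (see [loadAnnotation()]).
#' @param cfg A [CallerConfig-class].
#' @param codes gene-code table for isoform naming.
#' @return A [FusionIndex-class].
#' @export
fusionIndex <- function(genome, models, cfg = CallerConfig(),
                        codes = defaultGeneCodes()) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  anchorModel <- canonicalModel(models, cfg@anchorGene)
  anchorTx <- transcriptSeq(anchorModel, genome)
  nestedT0 <- firstMatch(cfg@nestedPrimer, anchorTx)
  if (is.na(nestedT0))
    stop("nested primer not found in the anchor gene transcript")
  ## canonical transcript per gene, sense strand
  geneIds <- unique(vapply(models, function(m) m@geneId, character(1)))
  txSeqs <- vapply(geneIds, function(g)
    transcriptSeq(canonicalModel(models, g), genome), character(1))
  names(txSeqs) <- paste0("tx:", vapply(geneIds, function(g)
    canonicalModel(models, g)@transcriptId, character(1)))
  gchar <- setNames(as.character(genome), names(genome))
  refSeqs <- c(gchar, setNames(as.character(reverseComplement(genome)),
                               paste0("rc:", names(genome))), txSeqs)
  kmers <- buildKmerIndex(refSeqs, cfg@kmerSize, bothStrands = FALSE)
  new("FusionIndex", kmers = kmers, k = cfg@kmerSize, refSeqs = refSeqs,
      refLen = setNames(nchar(refSeqs), names(refSeqs)), models = models,
      cfg = cfg, anchorModel = anchorModel, anchorTx = anchorTx,
      nestedT0 = as.integer(nestedT0), codes = codes)
}

## Map a position on an indexed reference to genomic coordinates.
## Returns list(chrom, pos, strand) where strand is the orientation of the
## retained (read-sense) sequence relative to the genome.
refToGenomic <- function(index, ref, pos) {
  if (startsWith(ref, "tx:")) {
    txId <- substring(ref, 4L)
    m <- index@models[[txId]]
    list(chrom = m@chrom, pos = transcriptToGenomic(m, pos),
         strand = m@strand)
  } else if (startsWith(ref, "rc:")) {
    chrom <- substring(ref, 4L)
    list(chrom = chrom, pos = index@refLen[[ref]] - pos + 1L, strand = "-")
  } else {
    list(chrom = ref, pos = pos, strand = "+")
  }
}

## Gene (canonical model) whose span contains a genomic position, or NULL.
geneAt <- function(index, chrom, pos) {
  for (m in index@models) {
    if (m@chrom != chrom) next
    sp <- geneSpan(m)
    if (pos >= sp[1] && pos <= sp[2])
      return(canonicalModel(index@models, m@geneId))
  }
  NULL
}
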