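## Deterministic toy reference: two sequences carrying an anchor-like gene
## pair (TMPRSS2-like upstream of ERG-like, mimicking the intra-chromosomal
## case) plus interchromosomal partner-like genes and a housekeeping gene.
## The anchor exon 1 embeds the real outer and nested primer sequences, in
## that order, reflecting that the nested primer hybridises closer to the
## expected breakpoint.

#' Generate the toy reference genome, annotation and manifest
#'
#' Builds a small deterministic two-chromosome reference for end-to-end
#' testing. `chrA` carries a 5-exon TMPRSS2-like anchor gene whose exon 1
#' contains the outer extension primer upstream of the nested indexing
#' primer, followed by a 6-exon coding ERG-like gene. `chrB` carries
#' partner-like genes (SIM2-like with 7 exons, PPP3CA-like, a minus-strand
#' AMACR-like gene) and a non-coding GAPDH-like housekeeping gene. Gene
#' structures are chosen so that exon-boundary, intronic, inverted-intronic
#' and reading-frame scenarios all have concrete loci.
#'
#' @param seed integer seed; the output is byte-identical for a fixed seed.
#' @param outPrefix path prefix; writes `<prefix>.fa`, `<prefix>.gtf` and
#'   `<prefix>_manifest.tsv`. With `NULL`, nothing is written.
#' @return (invisibly) a list with `genome` ([Biostrings::DNAStringSet]),
#'   `models` (named list of [GeneModel-class]), `manifest` (data.frame of
#'   embedded features) and, when written, the three file paths.
#' @examples
#' toy <- makeToyReference(seed = 1)
#' toy$models$TMPRSS2.t1
#' @export
makeToyReference <- function(seed = 1L, outPrefix = NULL) {
  built <- withSeed(deriveSeed(seed, 11L), buildToyGenome())
  nOcc <- countOccurrences(FTAS_NESTED_PRIMER, built$genome)
  if (nOcc != 1L)
    stop("nested primer not unique in toy genome (", nOcc, " occurrences)")
  res <- built
  if (!is.null(outPrefix)) {
    fasta <- paste0(outPrefix, ".fa")
    gtf <- paste0(outPrefix, ".gtf")
    manifest <- paste0(outPrefix, "_manifest.tsv")
    writeXStringSet(built$genome, fasta, width = 70L)
    writeLines(c("##gff-version 2", gtfLines(built$models)), gtf)
    write.table(built$manifest, manifest, sep = "\t", quote = FALSE,
                row.names = FALSE)
    res <- c(built, list(fasta = fasta, gtf = gtf, manifestFile = manifest))
  }
  invisible(res)
}

## Count occurrences of a pattern on both strands of a genome.
countOccurrences <- function(pattern, genome) {
  fwd <- sum(vapply(seq_along(genome), function(i)
    length(matchPattern(pattern, genome[[i]])), integer(1)))
  rev <- sum(vapply(seq_along(genome), function(i)
    length(matchPattern(revComp(pattern), genome[[i]])), integer(1)))
  fwd + rev
}

## Assemble both toy chromosomes. Coordinates are tracked while sequence
## pieces are emitted so the annotation is exact by construction.
buildToyGenome <- function() {
  manifest <- list()
  note <- function(type, name, chrom, start, end, strand, info = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      type = type, name = name, chrom = chrom, start = start, end = end,
      strand = strand, info = info, stringsAsFactors = FALSE)
  }

  newChrom <- function() new.env(parent = emptyenv())
  emit <- function(env, x) {
    seqs <- if (exists("pieces", envir = env)) get("pieces", envir = env)
            else character(0)
    cur <- if (exists("cur", envir = env)) get("cur", envir = env) else 1L
    s <- if (is.numeric(x)) randomDna(x) else x
    assign("pieces", c(seqs, s), envir = env)
    rng <- c(cur, cur + nchar(s) - 1L)
    assign("cur", cur + nchar(s), envir = env)
    rng
  }

  ## Emit a gene of alternating exon/intron widths; returns exon genomic
  ## ranges in transcript orientation. `exonSeqs` overrides exon content by
  ## transcript-exon index.
  emitGene <- function(env, strand, exonWidths, intronWidths,
                       exonSeqs = list()) {
    n <- length(exonWidths)
    stopifnot(length(intronWidths) == n - 1L)
    ## genomic (left-to-right) order of transcript exon indices
    gOrder <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    gIntron <- if (strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
    exRng <- vector("list", n)
    for (j in seq_len(n)) {
      ei <- gOrder[j]
      content <- if (!is.null(exonSeqs[[as.character(ei)]]))
        exonSeqs[[as.character(ei)]] else exonWidths[ei]
      exRng[[ei]] <- emit(env, content)
      if (j < n) emit(env, intronWidths[gIntron[j]])
    }
    do.call(rbind, exRng)
  }

  ## ---- chrA: anchor gene + intra-chromosomal partner ----
  A <- newChrom()
  emit(A, 150L)

  ## TMPRSS2-like exon 1: UTR pad, outer primer, spacer, nested primer, tail
  e1 <- paste0(randomDna(6L), FTAS_OUTER_PRIMER, randomDna(8L),
               FTAS_NESTED_PRIMER, randomDna(27L))
  tEx <- emitGene(A, "+", exonWidths = c(80L, 36L, 60L, 55L, 120L),
                  intronWidths = c(90L, 80L, 85L, 75L),
                  exonSeqs = list(`1` = e1))
  ## CDS: from the 5th base of exon 2 through the end of exon 5 (267 nt),
  ## so a junction at the exon 5 boundary sits exactly at the CDS end
  tCds <- rbind(c(tEx[2, 1] + 4L, tEx[2, 2]), tEx[3, ], tEx[4, ], tEx[5, ])
  emit(A, 250L)

  eEx <- emitGene(A, "+", exonWidths = c(70L, 64L, 58L, 66L, 72L, 130L),
                  intronWidths = c(100L, 90L, 120L, 95L, 88L))
  ## CDS: from 7th base of exon 2 through 100 bases of exon 6 (354 nt)
  eCds <- rbind(c(eEx[2, 1] + 6L, eEx[2, 2]), eEx[3, ], eEx[4, ], eEx[5, ],
                c(eEx[6, 1], eEx[6, 1] + 99L))
  emit(A, 150L)
  chrA <- paste(get("pieces", envir = A), collapse = "")

  ## ---- chrB: interchromosomal partners + housekeeping ----
  B <- newChrom()
  emit(B, 100L)
  sEx <- emitGene(B, "+", exonWidths = rep(50L, 7L),
                  intronWidths = c(70L, 70L, 70L, 70L, 70L, 120L))
  sCds <- rbind(c(sEx[1, 1] + 9L, sEx[1, 2]), sEx[2, ], sEx[3, ], sEx[4, ],
                sEx[5, ], sEx[6, ], c(sEx[7, 1], sEx[7, 1] + 41L))
  emit(B, 120L)
  pEx <- emitGene(B, "+", exonWidths = c(60L, 75L, 90L),
                  intronWidths = c(80L, 70L))
  ## phases arranged so a junction at the anchor exon 3 boundary joined to
  ## exon 2 here preserves the reading frame
  pCds <- rbind(c(pEx[1, 1] + 13L, pEx[1, 2]), pEx[2, ],
                c(pEx[3, 1], pEx[3, 1] + 87L))
  emit(B, 120L)
  aEx <- emitGene(B, "-", exonWidths = c(55L, 66L, 60L),
                  intronWidths = c(70L, 75L))
  ## minus strand: transcript 5' end is at the genomic right; CDS starts at
  ## the 8th transcript base of exon 1 (48 nt of exon 1 retained in CDS)
  aCds <- rbind(c(aEx[1, 1], aEx[1, 2] - 7L), aEx[2, ], aEx[3, ])
  emit(B, 120L)
  gEx <- emitGene(B, "+", exonWidths = c(300L, 300L), intronWidths = 80L)
  emit(B, 100L)
  chrB <- paste(get("pieces", envir = B), collapse = "")

  genome <- DNAStringSet(c(chrA = chrA, chrB = chrB))

  models <- list(
    TMPRSS2.t1 = GeneModel("TMPRSS2", "TMPRSS2", "chrA", "+", tEx, tCds),
    ERG.t1 = GeneModel("ERG", "ERG", "chrA", "+", eEx, eCds),
    SIM2.t1 = GeneModel("SIM2", "SIM2", "chrB", "+", sEx, sCds),
    PPP3CA.t1 = GeneModel("PPP3CA", "PPP3CA", "chrB", "+", pEx, pCds),
    AMACR.t1 = GeneModel("AMACR", "AMACR", "chrB", "-", aEx, aCds),
    GAPDH.t1 = GeneModel("GAPDH", "GAPDH", "chrB", "+", gEx, NULL)
  )

  for (m in models) {
    note("gene", m@symbol, m@chrom, min(IRanges::start(m@exons)),
         max(IRanges::end(m@exons)), m@strand,
         sprintf("%d exons%s", exonCount(m),
                 if (length(m@cds)) "; coding" else "; non-coding"))
  }
  op <- tEx[1, 1] + 6L
  note("outer_primer_site", FTAS_OUTER_PRIMER, "chrA", op,
       op + nchar(FTAS_OUTER_PRIMER) - 1L, "+",
       "anchor outer extension primer in TMPRSS2-like exon 1")
  np <- op + nchar(FTAS_OUTER_PRIMER) + 8L
  note("nested_primer_site", FTAS_NESTED_PRIMER, "chrA", np,
       np + nchar(FTAS_NESTED_PRIMER) - 1L, "+",
       "nested indexing primer, downstream of the outer primer")

  list(genome = genome, models = models,
       manifest = do.call(rbind, manifest))
}

#' Default gene-code table for isoform naming
#'
#' One-to-several-letter gene abbreviations used in fusion isoform names
#' (e.g. `T1-E4` for a TMPRSS2 exon 1 to ERG exon 4 junction). Unknown
#' genes are an error in [nameIsoform()] rather than a guessed code.
#'
#' @return Named character vector, names = gene symbols.
#' @export
defaultGeneCodes <- function() {
  c(TMPRSS2 = "T", ERG = "E", PPP3CA = "P", AMACR = "A", SIM2 = "S",
    TTC18 = "TTC", FGFR2 = "F", LINC00114 = "L", CASZ1 = "C", OPTN = "O",
    C1ORF61 = "C1", TBXAS1 = "TB", RERE = "R")
}
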