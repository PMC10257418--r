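## Anchored fusion caller: anchor verification, chimeric split mapping,
## molecular deduplication, junction clustering into calls, replicate
## concordance and reporting.
##
## Every on-target read pair starts at the nested primer inside the anchor
## gene, so the caller aligns R1 against the expected wild-type anchor
## transcript, detects the divergence point, seeds the divergent remainder
## (and R2) with exact k-mers over genome strands and canonical
## transcripts, and places the junction at the split maximising matched
## bases. The chimeric interpretation must beat the best single-locus
## (wild-type) alignment score (match +1, mismatch -1, no gaps within
## segments) and satisfy minimum segment and overhang lengths.

#' Verify the anchor primer prefix of R1
#'
#' @param r1 read sequence (trimmed).
#' @param cfg A [CallerConfig-class].
#' @return List: `accept`, `offset` (primer bases consumed), `mismatches`.
#' @export
checkAnchor <- function(r1, cfg = CallerConfig()) {
  pl <- nchar(cfg@nestedPrimer)
  if (nchar(r1) < pl)
    return(list(accept = FALSE, offset = NA_integer_, mismatches = NA_integer_))
  mm <- countMismatches(r1, cfg@nestedPrimer, pl)
  list(accept = mm <= cfg@anchorMaxMismatch, offset = pl, mismatches = mm)
}

#' Split-map one read pair
#'
#' Classifies a trimmed, anchor-checked pair as `"chimeric"` (with a
#' base-precise junction), `"wildtype"` (all segments consistent with the
#' anchor gene's transcript, including readthrough into its own introns),
#' `"off_target"` (R1 does not start with the nested primer) or
#' `"unmapped"`.
#'
#' @param r1,r2 trimmed read sequences.
#' @param index A [FusionIndex-class].
#' @param r1Complete does R1 span the entire insert (i.e. was it
#'   adapter-trimmed)? When `TRUE` the last R1 base is the termination
#'   base; when `FALSE` the termination coordinate is recovered from R2.
#' @return List with `status` and, for chimeric pairs, `alignment`: a
#'   one-row data.table with junction coordinates (1-based genomic),
#'   overhangs, mismatches, termination coordinate and ambiguity flag.
#' @export
splitMapPair <- function(r1, r2, index, r1Complete = TRUE) {
  res <- mapReadBatch(r1, r2, r1Complete, index)
  status <- res$status[1]
  if (status == "chimeric")
    list(status = status, alignment = res[1])
  else list(status = status, alignment = NULL)
}

## ---- batch mapping engine ----

alignmentCols <- function() {
  data.table(status = character(0), anchorChrom = character(0),
             anchorPos = integer(0), anchorStrand = character(0),
             anchorT = integer(0), partnerGene = character(0),
             partnerChrom = character(0), partnerPos = integer(0),
             partnerStrand = character(0), partnerT = integer(0),
             termPos = integer(0), overhang5 = integer(0),
             overhang3 = integer(0), mismatches = integer(0),
             ambiguous = logical(0))
}

## Vectorised classification of many pairs; returns one row per pair.
mapReadBatch <- function(r1, r2, r1Complete, index) {
  n <- length(r1)
  if (length(r1Complete) == 1L) r1Complete <- rep(r1Complete, n)
  cfg <- index@cfg
  pl <- nchar(cfg@nestedPrimer)
  len1 <- nchar(r1)
  out <- data.table(status = rep("unmapped", n), anchorChrom = NA_character_,
                    anchorPos = NA_integer_, anchorStrand = NA_character_,
                    anchorT = NA_integer_, partnerGene = NA_character_,
                    partnerChrom = NA_character_, partnerPos = NA_integer_,
                    partnerStrand = NA_character_, partnerT = NA_integer_,
                    termPos = NA_integer_, overhang5 = NA_integer_,
                    overhang3 = NA_integer_, mismatches = NA_integer_,
                    ambiguous = FALSE)
  if (n == 0L) return(out)

  W <- max(len1)
  M1 <- rawMatrix(r1, W)
  expRaw <- anchorExpected(index, W)

  ## anchor check (vectorised): mismatches within the primer prefix
  primerMM <- integer(n)
  for (j in seq_len(min(pl, W)))
    primerMM <- primerMM + (M1[, j] != expRaw[j])
  offTarget <- len1 < pl | primerMM > cfg@anchorMaxMismatch
  out$status[offTarget] <- "off_target"

  ## streaming divergence scan: first 6-nt window with >= 3 mismatches
  totalMM <- integer(n)
  divAt <- integer(n)            # 0 = none
  buf <- matrix(FALSE, n, 6L)
  for (j in seq_len(W)) {
    mmcol <- (M1[, j] != expRaw[j]) & (j <= len1)
    totalMM <- totalMM + mmcol
    buf[, ((j - 1L) %% 6L) + 1L] <- mmcol
    if (j >= 6L) {
      i <- j - 5L
      hit <- divAt == 0L & (rowSums(buf) >= 3L) & (j <= len1)
      divAt[hit] <- i
    }
  }
  softBudget <- pmax(2L, ceiling(0.02 * len1))
  plainWT <- !offTarget & divAt == 0L & totalMM <= softBudget & r1Complete
  out$status[plainWT] <- "wildtype"

  ## everything else (divergent, noisy, or R1 not spanning the insert)
  ## goes through the per-read junction engine, memoised on read content
  todo <- which(!offTarget & !plainWT)
  if (length(todo)) {
    key <- paste0(r1[todo], "\r", r2[todo], "\r", r1Complete[todo])
    uk <- !duplicated(key)
    res <- lapply(which(uk), function(ii) {
      i <- todo[ii]
      mapOnePair(r1[i], r2[i], r1Complete[i], divAt[i], totalMM[i], index)
    })
    resIdx <- match(key, key[uk])
    resAll <- rbindlist(res)[resIdx]
    for (col in names(resAll)) data.table::set(out, todo, col, resAll[[col]])
  }
  out
}

## Expected wild-type R1 content: anchor transcript bytes from the nested
## primer 5' end, zero-padded beyond the transcript end (always mismatch).
anchorExpected <- function(index, width) {
  s <- substr(index@anchorTx, index@nestedT0, nchar(index@anchorTx))
  b <- charToRaw(s)
  if (length(b) < width) b <- c(b, rep(as.raw(0L), width - length(b)))
  b[seq_len(width)]
}

## Full junction search for one pair. `divAt` is the vector prescreen's
## divergence estimate (0 if none), `totalMM` its anchor mismatch count.
mapOnePair <- function(r1, r2, r1Complete, divAt, totalMM, index) {
  cfg <- index@cfg
  len <- nchar(r1)
  softBudget <- max(2L, ceiling(0.02 * len))
  fit <- junctionSearch(r1, index, anchorOffset = index@nestedT0,
                        seedFrom = if (divAt > 0L) max(1L, divAt - 6L) else 1L)
  if (!is.null(fit) && fit$accepted) {
    return(finishChimeric(fit, r1, r2, r1Complete, index))
  }
  ## no acceptable junction in R1
  if (totalMM <= softBudget) {
    if (r1Complete) return(statusRow("wildtype"))
    return(r2Followup(r2, index))
  }
  statusRow("unmapped")
}

statusRow <- function(status) {
  out <- alignmentCols()[NA_integer_]
  out$status <- status
  out$ambiguous <- FALSE
  out
}

## Score-maximising split of `query` between the anchor transcript (aligned
## at transcript coordinate `anchorOffset` for query position 1) and a
## seeded partner locus. Returns NULL when no partner locus seeds at all.
junctionSearch <- function(query, index, anchorOffset, seedFrom = 1L) {
  cfg <- index@cfg
  k <- index@k
  len <- nchar(query)
  lo <- max(cfg@minSegment, cfg@minOverhang)
  if (len < 2L * lo) return(NULL)
  qb <- charToRaw(query)
  ## anchor prefix mismatch profile
  aEnd <- nchar(index@anchorTx) - anchorOffset + 1L
  expB <- charToRaw(substr(index@anchorTx, anchorOffset,
                           nchar(index@anchorTx)))
  expCmp <- rep(TRUE, len)          # TRUE = mismatch
  cmpLen <- min(len, aEnd)
  if (cmpLen > 0L) expCmp[seq_len(cmpLen)] <- qb[seq_len(cmpLen)] != expB[seq_len(cmpLen)]
  P <- cumsum(expCmp)
  scoreWT <- len - P[len]

  ## seed partner candidates
  starts <- unique(pmax(1L, c(seq.int(seedFrom, max(seedFrom, len - k + 1L),
                                      by = 4L), len - k + 1L)))
  starts <- starts[starts + k - 1L <= len]
  if (!length(starts)) return(NULL)
  seeds <- data.table(kmer = substring(query, starts, starts + k - 1L),
                      qpos = starts)
  hits <- index@kmers[seeds, on = "kmer", nomatch = NULL]
  if (nrow(hits)) hits[, diag := pos - qpos]
  ## partner tails shorter than k cannot carry a full k-mer seed; rescue
  ## them with an exact search of the terminal minOverhang bases
  tailLen <- cfg@minOverhang
  tailStart <- len - tailLen + 1L
  tailStr <- substr(query, tailStart, len)
  tailHits <- lapply(names(index@refSeqs), function(nm) {
    m <- gregexpr(tailStr, index@refSeqs[[nm]], fixed = TRUE)[[1]]
    if (m[1] == -1L) NULL
    else data.table(ref = nm, diag = as.integer(m) - tailStart, N = 1L)
  })
  cand <- rbindlist(c(
    if (nrow(hits)) list(hits[, .(N = .N), by = .(ref, diag)]),
    tailHits))
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- cand[, .(N = sum(N)), by = .(ref, diag)]
  setorder(cand, -N)
  cand <- cand[seq_len(min(12L, nrow(cand)))]

  ## the junction is located by unconstrained score maximisation; the
  ## segment and overhang minima are acceptance filters, so short-overhang
  ## reads are rejected rather than re-split inside the allowed range
  anchorEnds <- cumsum(IRanges::width(index@anchorModel@exons))
  best <- NULL
  bestScore <- -Inf
  bestJunctions <- character(0)
  for (ci in seq_len(nrow(cand))) {
    ref <- cand$ref[ci]; dg <- cand$diag[ci]
    refSeq <- index@refSeqs[[ref]]
    RL <- index@refLen[[ref]]
    qlo <- max(1L, 1L - dg); qhi <- min(len, RL - dg)
    match_ <- rep(FALSE, len)
    if (qhi >= qlo) {
      refB <- charToRaw(substr(refSeq, dg + qlo, dg + qhi))
      match_[qlo:qhi] <- qb[qlo:qhi] == refB
    }
    Tsuf <- rev(cumsum(rev(match_)))   # Tsuf[q] = matches in q..len
    Tsuf <- c(Tsuf, 0L)
    js <- 1L:(len - 1L)
    sc <- (js - P[js]) + Tsuf[js + 1L]
    mx <- max(sc)
    argj <- js[sc == mx]
    if (length(argj) > 1L) {
      onBoundary <- (anchorOffset - 1L + argj) %in% anchorEnds
      if (any(onBoundary)) argj <- argj[onBoundary]
    }
    j <- min(argj)
    if (mx > bestScore + 1e-9) {
      bestScore <- mx
      best <- list(ref = ref, diag = dg, j = j, score = mx, len = len,
                   P = P, scoreWT = scoreWT, anchorOffset = anchorOffset)
      bestJunctions <- sprintf("%s:%d", ref, dg + j + 1L)
    } else if (mx == bestScore) {
      g <- refToGenomic(index, ref, dg + j + 1L)
      gBest <- refToGenomic(index, best$ref, best$diag + best$j + 1L)
      if (!(g$chrom == gBest$chrom && g$pos == gBest$pos))
        bestJunctions <- union(bestJunctions,
                               sprintf("%s:%d", ref, dg + j + 1L))
    }
  }
  if (is.null(best)) return(NULL)
  best$ambiguous <- length(bestJunctions) > 1L
  best$accepted <- best$score > best$scoreWT &&
    best$j >= lo && (best$len - best$j) >= lo
  best
}

## Assemble the chimeric alignment record from an accepted junction fit.
finishChimeric <- function(fit, r1, r2, r1Complete, index) {
  cfg <- index@cfg
  j <- fit$j; len <- fit$len
  anchorT <- fit$anchorOffset - 1L + j
  am <- index@anchorModel
  anchorPos <- transcriptToGenomic(am, anchorT)
  g3 <- refToGenomic(index, fit$ref, fit$diag + j + 1L)
  gene3 <- geneAt(index, g3$chrom, g3$pos)
  if (is.null(gene3)) return(statusRow("unmapped"))
  if (gene3@geneId == am@geneId) return(statusRow("wildtype"))
  ## termination coordinate: last base of the insert on the partner side
  termRefPos <- NA_integer_
  if (r1Complete) {
    termRefPos <- min(fit$diag + len, index@refLen[[fit$ref]])
  } else if (nchar(r2) >= index@k) {
    rc2 <- revComp(r2)
    l2 <- nchar(rc2)
    tl <- index@kmers[.(substr(rc2, l2 - index@k + 1L, l2)),
                      on = "kmer", nomatch = NULL]
    tl <- tl[ref == fit$ref & pos + index@k - 1L >= fit$diag + j]
    termRefPos <- if (nrow(tl)) min(tl$pos) + index@k - 1L
                  else min(fit$diag + len, index@refLen[[fit$ref]])
  } else {
    termRefPos <- min(fit$diag + len, index@refLen[[fit$ref]])
  }
  gt <- refToGenomic(index, fit$ref, termRefPos)
  out <- alignmentCols()[NA_integer_]
  out$status <- "chimeric"
  out$anchorChrom <- am@chrom
  out$anchorPos <- anchorPos
  out$anchorStrand <- am@strand
  out$anchorT <- anchorT
  out$partnerGene <- gene3@geneId
  out$partnerChrom <- g3$chrom
  out$partnerPos <- g3$pos
  out$partnerStrand <- g3$strand
  out$partnerT <- if (g3$strand == gene3@strand)
    tryCatch(genomicToTranscript(gene3, g3$pos), error = function(e)
      NA_integer_) else NA_integer_
  out$termPos <- gt$pos
  out$overhang5 <- j
  out$overhang3 <- len - j
  out$mismatches <- as.integer(len - fit$score)
  out$ambiguous <- fit$ambiguous
  out
}

## Junction search in R2 for pairs whose R1 is wild-type-consistent but
## does not span the insert (long inserts): align the reverse complement
## of R2 to the anchor transcript at a seeded offset, then split.
r2Followup <- function(r2, index) {
  k <- index@k
  rc2 <- revComp(r2)
  if (nchar(rc2) < k) return(statusRow("wildtype"))
  anchorRef <- paste0("tx:", index@anchorModel@transcriptId)
  h <- index@kmers[.(substr(rc2, 1L, k)), on = "kmer", nomatch = NULL]
  h <- h[ref == anchorRef]
  if (nrow(h) == 0L) return(statusRow("unmapped"))
  bestRow <- statusRow("wildtype")
  for (o in h$pos) {
    exp_ <- substr(index@anchorTx, o, o + nchar(rc2) - 1L)
    mm <- countMismatches(rc2, exp_) + (nchar(rc2) - nchar(exp_))
    if (mm <= max(2L, ceiling(0.02 * nchar(rc2)))) return(statusRow("wildtype"))
    fit <- junctionSearch(rc2, index, anchorOffset = o, seedFrom = 1L)
    if (!is.null(fit) && fit$accepted)
      return(finishChimeric(fit, rc2, "", TRUE, index))
  }
  bestRow
}

## ---- deduplication, clustering, concordance ----

#' Collapse PCR duplicates of chimeric alignments
#'
#' Because every on-target molecule starts at the same primer, the
#' termination coordinate of the dideoxy-terminated base is the sole
#' molecular identifier (no UMI): alignments sharing the junction, the
#' retained-segment strand and the termination coordinate are copies of
#' one original molecule.
#'
#' @param alignments data.table of chimeric alignments (see
#'   [splitMapPair()]); non-chimeric rows are ignored.
#' @return data.table of unique fragments with a `reads` weight column.
#' @export
deduplicateAlignments <- function(alignments) {
  al <- alignments[status == "chimeric"]
  if (nrow(al) == 0L) {
    out <- alignmentCols()
    out[, reads := integer(0)]
    return(out)
  }
  al[, .(overhang5 = overhang5[1], overhang3 = overhang3[1],
         mismatches = min(mismatches), reads = .N),
     by = .(status, anchorChrom, anchorPos, anchorStrand, anchorT,
            partnerGene, partnerChrom, partnerPos, partnerStrand, partnerT,
            termPos, ambiguous)]
}

#' Cluster deduplicated alignments into fusion calls
#'
#' Fragments are grouped by gene pair and junction (within
#' `junctionMergeWindow` nt); each group is reported at its modal junction
#' with aggregated counts, an isoform name, a junction-structure class, a
#' reading-frame class and an evidence-based confidence tier. Ambiguous
#' alignments are excluded from the counts.
#'
#' @param fragments output of [deduplicateAlignments()].
#' @param index A [FusionIndex-class].
#' @return data.table of calls, one row per junction cluster.
#' @export
clusterCalls <- function(fragments, index) {
  cfg <- index@cfg
  fr <- fragments[status == "chimeric" & ambiguous == FALSE]
  if (nrow(fr) == 0L) return(emptyCalls())
  setorder(fr, partnerGene, partnerChrom, partnerStrand, partnerPos,
           anchorPos)
  ## single-link clustering of the distinct junctions: junctions merge
  ## when near in transcript space, or when related by a shift along
  ## (near-)homologous reference flanks -- the same molecular junction can
  ## be reported at shifted coordinates when a sequencing error inside a
  ## micro-homology tract rescues the shifted split
  jx <- unique(fr[, .(partnerGene, partnerChrom, partnerStrand, partnerPos,
                      partnerT, anchorPos, anchorT)])
  nj <- nrow(jx)
  parent <- seq_len(nj)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nj > 1L) {
    for (i in 1:(nj - 1L)) for (k in (i + 1L):nj) {
      if (jx$partnerGene[i] != jx$partnerGene[k] ||
          jx$partnerStrand[i] != jx$partnerStrand[k] ||
          jx$partnerChrom[i] != jx$partnerChrom[k]) next
      if (junctionsEquivalent(jx[i], jx[k], index)) {
        ri <- findRoot(i); rk <- findRoot(k)
        if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
      }
    }
  }
  roots <- vapply(seq_len(nj), findRoot, integer(1))
  jx[, cluster := as.integer(factor(roots))]
  fr <- merge(fr, jx,
              by = c("partnerGene", "partnerChrom", "partnerStrand",
                     "partnerPos", "partnerT", "anchorPos", "anchorT"),
              sort = FALSE)
  calls <- fr[, {
    ## modal junction: the distinct junction with the most supporting
    ## reads in the cluster (ties: more fragments, then leftmost)
    byJx <- .SD[, .(r = sum(reads), f = .N),
                by = .(anchorChrom, anchorPos, anchorStrand, anchorT,
                       partnerChrom, partnerPos, partnerStrand, partnerT)]
    setorder(byJx, -r, -f, anchorPos, partnerPos)
    modal <- byJx[1]
    .(anchorChrom = modal$anchorChrom, anchorPos = modal$anchorPos,
      anchorStrand = modal$anchorStrand, anchorT = modal$anchorT,
      partnerGene = partnerGene[1],
      partnerChrom = modal$partnerChrom, partnerPos = modal$partnerPos,
      partnerStrand = modal$partnerStrand, partnerT = modal$partnerT,
      splitReads = sum(reads), uniqueFragments = .N,
      distinctTerminations = data.table::uniqueN(termPos))
  }, by = cluster]
  calls <- calls[splitReads >= cfg@minSplitReads]
  if (nrow(calls) == 0L) return(emptyCalls())
  calls[, confidence := ifelse(
    uniqueFragments >= cfg@highMinFragments &
      distinctTerminations >= cfg@highMinTerminations, "high",
    ifelse(uniqueFragments >= cfg@mediumMinFragments, "medium", "low"))]
  annotateCalls(calls, index)
}

## Junction proximity in transcript space where both coordinates are
## exonic (a one-base shift across an intron is one transcript base, not
## one intron length), genomic space otherwise.
junctionNear <- function(posA, txA, posB, txB, w) {
  if (!is.na(txA) && !is.na(txB)) abs(txA - txB) <= w
  else abs(posA - posB) <= w
}

## Are two called junctions reports of the same molecular junction?
## Either near (within the merge window on both sides), or related by a
## coordinated shift s on both sides whose s flanking reference bases are
## homologous up to one mismatch: within such a tract the split position
## is not determined by the read, and one error can make a shifted split
## score best.
junctionsEquivalent <- function(a, b, index) {
  w <- index@cfg@junctionMergeWindow
  if (junctionNear(a$partnerPos, a$partnerT, b$partnerPos, b$partnerT, w) &&
      junctionNear(a$anchorPos, a$anchorT, b$anchorPos, b$anchorT, w))
    return(TRUE)
  sA <- b$anchorT - a$anchorT
  sP <- if (!is.na(a$partnerT) && !is.na(b$partnerT)) b$partnerT - a$partnerT
        else if (a$partnerStrand == "+") b$partnerPos - a$partnerPos
        else a$partnerPos - b$partnerPos
  if (sA != sP || sA == 0L || abs(sA) > index@cfg@minOverhang) return(FALSE)
  left <- if (sA > 0L) a else b
  s <- abs(sA)
  anchorFlank <- substr(index@anchorTx, left$anchorT + 1L, left$anchorT + s)
  partnerFlank <- retainedSeq(index, left, s)
  if (nchar(anchorFlank) != s || is.na(partnerFlank) ||
      nchar(partnerFlank) != s)
    return(FALSE)
  countMismatches(anchorFlank, partnerFlank, s) <= 1L
}

## First `s` partner bases of a junction, in retained (read) orientation.
retainedSeq <- function(index, junction, s) {
  if (!is.na(junction$partnerT)) {
    m <- canonicalModel(index@models, junction$partnerGene)
    tx <- index@refSeqs[[paste0("tx:", m@transcriptId)]]
    if (is.null(tx)) return(NA_character_)
    return(substr(tx, junction$partnerT, junction$partnerT + s - 1L))
  }
  chromSeq <- index@refSeqs[[junction$partnerChrom]]
  if (is.null(chromSeq)) return(NA_character_)
  p <- junction$partnerPos
  if (junction$partnerStrand == "+") substr(chromSeq, p, p + s - 1L)
  else revComp(substr(chromSeq, p - s + 1L, p))
}

emptyCalls <- function() {
  data.table(cluster = integer(0), anchorChrom = character(0),
             anchorPos = integer(0), anchorStrand = character(0),
             anchorT = integer(0), partnerGene = character(0),
             partnerChrom = character(0), partnerPos = integer(0),
             partnerStrand = character(0), partnerT = integer(0),
             splitReads = integer(0), uniqueFragments = integer(0),
             distinctTerminations = integer(0), confidence = character(0),
             isoform = character(0), junctionType = character(0),
             frame = character(0))
}

## Attach isoform names, junction structure and reading frame via the
## gene-model layer.
annotateCalls <- function(calls, index) {
  am <- index@anchorModel
  defs <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    bp5 <- classifyBreakpoint(am, calls$anchorPos[i], "five_prime", "+")
    g3 <- canonicalModel(index@models, calls$partnerGene[i])
    bp3 <- classifyBreakpoint(g3, calls$partnerPos[i], "three_prime",
                              calls$partnerStrand[i])
    defs[[i]] <- FusionDefinition(am, bp5, g3, bp3)
  }
  calls[, junctionType := vapply(defs, function(d)
    d@threeBreakpoint@feature, character(1))]
  ## disambiguating letters need the sibling intronic breakpoints observed
  ## in the same gene and intron across the whole call set
  isoforms <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    d <- defs[[i]]
    sibs <- NULL
    if (d@threeBreakpoint@feature == "intronic") {
      same <- which(calls$partnerGene == calls$partnerGene[i] &
                      calls$junctionType == "intronic" &
                      vapply(defs, function(x) x@threeBreakpoint@index,
                             integer(1)) == d@threeBreakpoint@index)
      sibs <- calls$partnerPos[same]
    }
    isoforms[i] <- nameIsoform(d, index@codes, siblingPositions = sibs)
  }
  calls[, isoform := isoforms]
  calls[, frame := vapply(defs, function(d)
    classifyReadingFrame(d, index@models), character(1))]
  calls[]
}

## Classify a called genomic breakpoint against a gene model.
classifyBreakpoint <- function(m, pos, side, retainedStrand) {
  ex <- m@exons
  inExon <- which(pos >= IRanges::start(ex) & pos <= IRanges::end(ex))
  ir <- intronRanges(m)
  inIntron <- which(pos >= IRanges::start(ir) & pos <= IRanges::end(ir))
  inverted <- retainedStrand != m@strand
  if (length(inExon)) {
    idx <- inExon[1]
    edge <- if (side == "five_prime") exonEdge3(m, idx) else exonEdge5(m, idx)
    feature <- if (!inverted && pos == edge) "exon_boundary"
               else if (inverted) "inverted_intronic" else "exonic_internal"
    ## an inverted segment landing in an exon is labelled with the exon
    ## index; only intron-contained inversions use intron numbering
    if (feature == "inverted_intronic" && side == "three_prime")
      return(Breakpoint(m@chrom, pos, side, "inverted_intronic", idx,
                        retainedStrand))
    return(Breakpoint(m@chrom, pos, side, feature, idx, retainedStrand))
  }
  if (length(inIntron)) {
    idx <- inIntron[1]
    feature <- if (inverted && side == "three_prime") "inverted_intronic"
               else "intronic"
    return(Breakpoint(m@chrom, pos, side, feature, idx, retainedStrand))
  }
  stop("position ", pos, " not inside gene ", m@symbol)
}

#' Replicate concordance filter
#'
#' Retains calls whose gene pair and junction (within the merge window)
#' occur in both technical replicates; per-replicate fragment counts are
#' reported. With `requireBothReplicates = FALSE` the union is returned
#' with a `bothReplicates` flag instead.
#'
#' @param callsRep1,callsRep2 per-replicate call tables from
#'   [clusterCalls()].
#' @param cfg A [CallerConfig-class].
#' @return data.table of final calls.
#' @export
replicateConcordance <- function(callsRep1, callsRep2, cfg = CallerConfig()) {
  w <- cfg@junctionMergeWindow
  matchOf <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      if (nrow(b) == 0L) return(NA_integer_)
      near <- vapply(seq_len(nrow(b)), function(k) {
        b$partnerGene[k] == a$partnerGene[i] &&
          b$partnerStrand[k] == a$partnerStrand[i] &&
          junctionNear(b$partnerPos[k], b$partnerT[k], a$partnerPos[i],
                       a$partnerT[i], w) &&
          junctionNear(b$anchorPos[k], b$anchorT[k], a$anchorPos[i],
                       a$anchorT[i], w)
      }, logical(1))
      j <- which(near)
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
  }
  if (nrow(callsRep1) == 0L && nrow(callsRep2) == 0L) {
    out <- emptyCalls()
    out[, `:=`(rep1Fragments = integer(0), rep2Fragments = integer(0),
               bothReplicates = logical(0))]
    return(out)
  }
  m12 <- if (nrow(callsRep1)) matchOf(callsRep1, callsRep2) else integer(0)
  merged <- copy(callsRep1)
  merged[, rep1Fragments := uniqueFragments]
  merged[, rep2Fragments := ifelse(is.na(m12), 0L,
                                   callsRep2$uniqueFragments[m12])]
  merged[, bothReplicates := !is.na(m12)]
  if (!is.na(m12[1]) || TRUE) {
    ## aggregate evidence across replicates for matched calls
    matched <- which(!is.na(m12))
    if (length(matched)) {
      merged$splitReads[matched] <- merged$splitReads[matched] +
        callsRep2$splitReads[m12[matched]]
      merged$uniqueFragments[matched] <- merged$uniqueFragments[matched] +
        callsRep2$uniqueFragments[m12[matched]]
      merged$distinctTerminations[matched] <-
        merged$distinctTerminations[matched] +
        callsRep2$distinctTerminations[m12[matched]]
    }
  }
  if (cfg@requireBothReplicates) {
    merged <- merged[bothReplicates == TRUE]
  } else {
    only2 <- setdiff(seq_len(nrow(callsRep2)),
                     m12[!is.na(m12)])
    if (length(only2)) {
      extra <- copy(callsRep2[only2])
      extra[, `:=`(rep1Fragments = 0L, rep2Fragments = uniqueFragments,
                   bothReplicates = FALSE)]
      merged <- rbindlist(list(merged, extra), use.names = TRUE)
    }
  }
  merged[]
}
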