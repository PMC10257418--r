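test_that("k-mer index covers every position on both strands", {
  s <- ftasseq:::withSeed(7, paste(sample(c("A", "C", "G", "T"), 100,
                                          replace = TRUE), collapse = ""))
  idx <- buildKmerIndex(c(s1 = s), k = 15L)
  expect_equal(sum(idx$strand == "+"), 86L)
  expect_equal(sum(idx$strand == "-"), 86L)
  expect_equal(nrow(idx[idx$kmer == strrep("A", 15)]), 0L)
  ## planted unique 15-mer is recovered at exactly its locus
  planted <- "ACGTTGCAAGGTCCA"
  s2 <- paste0(substr(s, 1, 40), planted, substr(s, 56, 100))
  idx2 <- buildKmerIndex(c(s1 = s2), k = 15L)
  hit <- idx2[idx2$kmer == planted & idx2$strand == "+"]
  bruteForce <- gregexpr(planted, s2, fixed = TRUE)[[1]]
  expect_equal(hit$pos, as.integer(bruteForce))
  expect_equal(length(bruteForce), 1L)
  expect_error(buildKmerIndex(c(a = s, a = s), 15L), "duplicate")
  expect_error(buildKmerIndex(c(a = s), 5L), ">= 8")
})

test_that("caller config validity enforces seed/segment consistency", {
  expect_error(CallerConfig(kmerSize = 20L, minSegment = 10L), "minSegment")
  expect_error(CallerConfig(kmerSize = 7L), ">= 8")
  expect_error(CallerConfig(minOverhang = 0L), "minOverhang")
})

test_that("anchor check accepts the primer prefix within one mismatch", {
  cfg <- CallerConfig()
  good <- paste0("GGAGGCGGAGGGCGAGGG", strrep("ACGT", 20))
  expect_true(checkAnchor(good, cfg)$accept)
  oneMM <- paste0("GGAGGCGGAGGTCGAGGG", strrep("ACGT", 20))
  expect_true(checkAnchor(oneMM, cfg)$accept)
  twoMM <- paste0("GGAGGCGGTGGTCGAGGG", strrep("ACGT", 20))
  expect_false(checkAnchor(twoMM, cfg)$accept)
  expect_false(checkAnchor("GGA", cfg)$accept)
})

test_that("split mapping places fusion junctions base-precisely", {
  toy <- toyRef()
  index <- toyIndex()
  erg <- toy$models$ERG.t1
  ## T1-E4: anchor part is 45 nt past the nested primer start
  pair <- cleanFusionPair("T1-E4", insertLen = 80L)
  res <- splitMapPair(pair$insert, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(pair$insert))),
    index)
  expect_equal(res$status, "chimeric")
  al <- res$alignment
  expect_equal(al$anchorPos, ftasseq:::exonEdge3(toy$models$TMPRSS2.t1, 1L))
  expect_equal(al$partnerPos, ftasseq:::exonEdge5(erg, 4L))
  expect_equal(al$partnerGene, "ERG")
  expect_equal(al$overhang5, 45L)
  expect_equal(al$overhang3, 35L)
  expect_equal(al$mismatches, 0L)
  ## termination coordinate = genomic position of the insert's last base
  expect_equal(al$termPos,
               transcriptToGenomic(erg, ftasseq:::genomicToTranscript(
                 erg, ftasseq:::exonEdge5(erg, 4L)) + 34L))
})

test_that("short partner overhangs are not called chimeric", {
  index <- toyIndex()
  pair <- cleanFusionPair("T1-E4", insertLen = 53L)   # 8 nt past junction
  res <- splitMapPair(pair$insert, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(pair$insert))),
    index)
  expect_false(identical(res$status, "chimeric"))
  pair2 <- cleanFusionPair("T1-E4", insertLen = 56L)  # 11 nt overhang
  res2 <- splitMapPair(pair2$insert, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(pair2$insert))),
    index)
  expect_equal(res2$status, "chimeric")
})

test_that("wild-type and off-target reads are classified as such", {
  index <- toyIndex()
  wt <- cleanFusionPair("WT", insertLen = 100L)
  expect_equal(splitMapPair(wt$insert, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(wt$insert))),
    index)$status, "wildtype")
  ## housekeeping-derived read: no anchor primer
  toy <- toyRef()
  hk <- substr(transcriptSeq(toy$models$GAPDH.t1, toy$genome), 1, 120)
  expect_equal(splitMapPair(hk, hk, index)$status, "off_target")
})

test_that("junctions crossing a partner splice site still map", {
  toy <- toyRef()
  index <- toyIndex()
  ## long T1-E4 insert: the partner side spans the exon 4 | exon 5 splice
  pair <- cleanFusionPair("T1-E4", insertLen = 130L)
  res <- splitMapPair(pair$insert, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(pair$insert))),
    index)
  expect_equal(res$status, "chimeric")
  expect_equal(res$alignment$partnerPos,
               ftasseq:::exonEdge5(toy$models$ERG.t1, 4L))
})

test_that("inverted intronic partners are called on the opposite strand", {
  toy <- toyRef()
  index <- toyIndex()
  pair <- cleanFusionPair("T5-SVI", insertLen = 340L)
  tr <- trimPairs(pair$r1, pair$r2, pair$q1, pair$q2, TrimConfig())
  res <- splitMapPair(tr$r1, tr$r2, index, r1Complete = tr$insertComplete)
  expect_equal(res$status, "chimeric")
  expect_equal(res$alignment$partnerGene, "SIM2")
  expect_equal(res$alignment$partnerStrand, "-")
})

test_that("deduplication collapses by junction and termination coordinate", {
  mk <- function(term, anchor = 230L, partner = 1584L) {
    out <- ftasseq:::alignmentCols()[NA_integer_]
    out$status <- "chimeric"; out$anchorChrom <- "chrA"
    out$anchorPos <- anchor; out$anchorStrand <- "+"; out$anchorT <- 80L
    out$partnerGene <- "ERG"; out$partnerChrom <- "chrA"
    out$partnerPos <- partner; out$partnerStrand <- "+"; out$partnerT <- 193L
    out$termPos <- as.integer(term); out$overhang5 <- 45L
    out$overhang3 <- 30L; out$mismatches <- 0L; out$ambiguous <- FALSE
    out
  }
  al <- data.table::rbindlist(list(mk(1600), mk(1600), mk(1601)))
  dd <- deduplicateAlignments(al)
  expect_equal(nrow(dd), 2L)
  expect_equal(sort(dd$reads), c(1L, 2L))
  ## idempotence: deduplicating unique fragments changes nothing
  dd2 <- deduplicateAlignments(dd[, -"reads"])
  expect_equal(nrow(dd2), nrow(dd))
  ## permutation invariance
  perm <- al[c(3, 1, 2)]
  ddp <- deduplicateAlignments(perm)
  data.table::setorder(dd, termPos); data.table::setorder(ddp, termPos)
  expect_identical(dd, ddp)
  expect_equal(nrow(deduplicateAlignments(al[0])), 0L)
})

test_that("clustering aggregates evidence and assigns confidence tiers", {
  index <- toyIndex()
  mk <- function(term, anchor = 230L, anchorT = 80L, partner = 1584L,
                 partnerT = 193L, reads = 1L) {
    data.table::data.table(
      status = "chimeric", anchorChrom = "chrA", anchorPos = anchor,
      anchorStrand = "+", anchorT = anchorT, partnerGene = "ERG",
      partnerChrom = "chrA", partnerPos = partner, partnerStrand = "+",
      partnerT = partnerT, termPos = as.integer(term), overhang5 = 45L,
      overhang3 = 30L, mismatches = 0L, ambiguous = FALSE, reads = reads)
  }
  ## 12 fragments, 7 distinct terminations -> one high-confidence call
  fr <- data.table::rbindlist(lapply(1:12, function(i)
    mk(1600 + (i %% 7), reads = 2L)))
  calls <- clusterCalls(fr, index)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$uniqueFragments, 12L)
  expect_equal(calls$distinctTerminations, 7L)
  expect_equal(calls$splitReads, 24L)
  expect_equal(calls$confidence, "high")
  expect_equal(calls$isoform, "T1-E4")
  ## single fragment -> low confidence
  expect_equal(clusterCalls(mk(1700), index)$confidence, "low")
  ## junctions 2 nt apart merge at the modal coordinate
  near <- data.table::rbindlist(list(
    mk(1600, reads = 3L), mk(1601, anchor = 228L, anchorT = 78L,
                             partner = 1582L, partnerT = 191L)))
  merged <- clusterCalls(near, index)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$anchorPos, 230L)
  expect_equal(merged$partnerPos, 1584L)
  ## ambiguous fragments are excluded from the counts
  amb <- mk(1666); amb$ambiguous <- TRUE
  expect_equal(nrow(clusterCalls(amb, index)), 0L)
})

test_that("replicate concordance keeps only junctions seen in both", {
  index <- toyIndex()
  cfg <- index@cfg
  mkCall <- function(partner = 1584L, partnerT = 193L, frags = 5L) {
    fr <- data.table::data.table(
      status = "chimeric", anchorChrom = "chrA", anchorPos = 230L,
      anchorStrand = "+", anchorT = 80L, partnerGene = "ERG",
      partnerChrom = "chrA", partnerPos = partner, partnerStrand = "+",
      partnerT = partnerT,
      termPos = as.integer(partner + seq_len(frags) + 20L),
      overhang5 = 45L, overhang3 = 30L, mismatches = 0L, ambiguous = FALSE,
      reads = 1L)
    clusterCalls(fr, index)
  }
  both <- replicateConcordance(mkCall(), mkCall(frags = 3L), cfg)
  expect_equal(nrow(both), 1L)
  expect_equal(both$rep1Fragments, 5L)
  expect_equal(both$rep2Fragments, 3L)
  only1 <- replicateConcordance(mkCall(), mkCall(partner = 1745L,
                                                 partnerT = 259L), cfg)
  expect_equal(nrow(only1), 0L)
  empty <- replicateConcordance(ftasseq:::emptyCalls(),
                                ftasseq:::emptyCalls(), cfg)
  expect_equal(nrow(empty), 0L)
  ## union mode flags single-replicate calls instead of dropping them
  cfgU <- CallerConfig(requireBothReplicates = FALSE)
  uni <- replicateConcordance(mkCall(), mkCall(partner = 1745L,
                                               partnerT = 259L), cfgU)
  expect_equal(nrow(uni), 2L)
  expect_equal(sum(uni$bothReplicates), 0L)
})

test_that("raising the minimum overhang never adds calls", {
  sim <- toySim()
  toy <- toyRef()
  nCalls <- vapply(c(10L, 25L, 45L), function(oh) {
    cfg <- CallerConfig(minOverhang = oh)
    res <- callFusions(sim$r1, sim$r2, toy$genome, toy$models, cfg = cfg)
    nrow(res$calls)
  }, integer(1))
  expect_true(all(diff(nCalls) <= 0))
})

test_that("the fusion report has the fixed column contract", {
  index <- toyIndex()
  dir <- file.path(tempdir(), "report-test")
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "fusions.tsv")
  ## header is emitted even with zero calls
  empty <- ftasseq:::emptyCalls()
  empty[, `:=`(rep1Fragments = integer(0), rep2Fragments = integer(0),
               bothReplicates = logical(0))]
  writeFusionReport(empty, data.table::data.table(), path, index@cfg, 1L)
  lines <- readLines(path)
  hdr <- lines[!startsWith(lines, "#")]
  expect_equal(hdr[1], paste(
    c("gene5", "gene3", "breakpoint5", "breakpoint3", "isoform_name",
      "junction_type", "split_reads", "unique_fragments",
      "distinct_terminations", "confidence", "reading_frame",
      "rep1_fragments", "rep2_fragments"), collapse = "\t"))
  expect_equal(length(hdr), 1L)
  expect_true(any(grepl("confidence tiers", lines[startsWith(lines, "#")])))
})

test_that("caller requires matching replicate structure", {
  sim <- toySim()
  toy <- toyRef()
  expect_error(callFusions(sim$r1, sim$r2[1], toy$genome, toy$models),
               "same number")
  expect_error(callFusions(sim$r1[1], sim$r2[1], toy$genome, toy$models,
                           cfg = CallerConfig(requireBothReplicates = TRUE)),
               "2 replicates")
})
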