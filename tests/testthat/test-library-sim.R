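test_that("termination probabilities derive from concentration competition", {
  p <- terminationProbs(NucleotideMix())
  expect_equal(unname(p["C"]), 0.1)
  expect_equal(unname(p["T"]), 0.1)
  p2 <- terminationProbs(NucleotideMix(dCTP = 0.5, ddC_ON = 0.5,
                                       dTTP = 1, ddU_ON = 0))
  expect_equal(unname(p2["C"]), 0.5)
  expect_equal(unname(p2["T"]), 0)
  expect_error(NucleotideMix(dCTP = 0, ddC_ON = 0), "positive")
})

test_that("extension terminates at the stated per-pyrimidine frequency", {
  tpl <- paste0("CCCCC", "TAGGCGCGAGCTAAGCAGGAG",
                ftasseq:::withSeed(5, paste(sample(c("A", "C", "G", "T"), 400,
                                                   replace = TRUE),
                                            collapse = "")))
  res <- extendWithTerminators(tpl, "TAGGCGCGAGCTAAGCAGGAG",
                               NucleotideMix(), cycles = 8000L, seed = 2L)
  freq <- sum(res$terminated) / sum(res$nPyr)
  expect_gt(sum(res$nPyr), 50000)
  expect_lt(abs(freq - 0.1), 0.01)
  ## terminator-terminated strands end on a pyrimidine
  expect_true(all(res$terminalBase[res$terminated] %in% c("C", "T")))
})

test_that("templates without nascent pyrimidines run to the template end", {
  tpl <- paste0("TAGGCGCGAGCTAAGCAGGAG", strrep("AG", 50))
  res <- extendWithTerminators(tpl, "TAGGCGCGAGCTAAGCAGGAG",
                               NucleotideMix(), cycles = 50L, seed = 1L)
  expect_true(all(!res$terminated))
  expect_true(all(res$end == nchar(tpl)))
  ## absent primer site is target depletion, not an error
  expect_equal(nrow(extendWithTerminators(strrep("ACGT", 50), "TTTTTTTTTT",
                                          NucleotideMix(), 5L, 1L)), 0L)
})

test_that("termination counts on alternating C/A follow the geometric law", {
  tpl <- paste0("TAGGCGCGAGCTAAGCAGGAG", strrep("CA", 3000))
  res <- extendWithTerminators(tpl, "TAGGCGCGAGCTAAGCAGGAG",
                               NucleotideMix(), cycles = 10000L, seed = 3L)
  term <- res[res$terminated == TRUE]
  ## nascent nucleotides to termination: pyrimidines sit at odd offsets, so
  ## the walk length is 2k - 1 for the k-th pyrimidine
  expect_true(all((term$end - 21L) %% 2L == 1L))
  k <- term$nPyr
  ## chi-square goodness of fit against Geometric(0.1), pooled tail
  kmax <- 40L
  obs <- tabulate(pmin(k, kmax), nbins = kmax)
  pr <- dgeom(0:(kmax - 2L), 0.1)
  pr <- c(pr, 1 - sum(pr))
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("degradation fragments at the configured per-bond rate", {
  L <- 1000L
  pool <- data.frame(id = "tx", sequence = strrep("A", L), abundance = 1)
  ## oligo-dT on intact RNA: every span covers the whole transcript
  intact <- degradeAndReverseTranscribe(pool, 0, 500L, seed = 1L,
                                        randomPrimingFraction = 0)
  expect_true(all(intact$spans$start == 1L & intact$spans$end == L))
  ## expected mean fragment length L / (1 + (L-1) p)
  rt <- degradeAndReverseTranscribe(pool, 0.01, 10000L, seed = 2L,
                                    randomPrimingFraction = 0)
  fragLen <- rt$spans$end - rt$spans$start + 1L
  expected <- L / (1 + (L - 1) * 0.01)
  expect_lt(abs(mean(fragLen) - expected), 3)
  expect_error(degradeAndReverseTranscribe(pool[0, ], 0, 10L), "empty")
})

test_that("molecule sampling recovers configured abundance ratios", {
  pool <- data.frame(id = c("fusion", "hk"),
                     sequence = strrep("A", c(300, 300)),
                     abundance = c(1, 1000))
  rt <- degradeAndReverseTranscribe(pool, 0, 100000L, seed = 4L)
  nf <- rt$counts$molecules[rt$counts$transcript == "fusion"]
  expect_lt(abs(nf - 100000 / 1001), 3 * sqrt(100000 / 1001))
})

test_that("nested PCR re-anchors, size-selects and amplifies", {
  cfgBase <- LibraryConfig(seed = 1L)
  tx <- c(t1 = paste0(strrep("G", 10), "GGAGGCGGAGGGCGAGGG",
                      strrep("ACTG", 100)))
  nStart <- 11L
  mk <- function(ends) data.table::data.table(
    transcript = "t1", spanStart = 1L, end = as.integer(ends))
  ## terminated 5 nt after the nested primer: below the size window
  short <- nestedPcrSizeSelect(mk(nStart + 18L + 5L), tx, cfgBase, seed = 1L)
  expect_equal(nrow(short), 0L)
  ## molecules not covering the nested primer site are dropped
  noSite <- nestedPcrSizeSelect(mk(20L), tx, cfgBase, seed = 1L)
  expect_equal(nrow(noSite), 0L)
  ## zero efficiency: survivors carry duplicateCount 1
  cfg0 <- LibraryConfig(pcrEfficiency = 0, seed = 1L)
  surv <- nestedPcrSizeSelect(mk(rep(nStart + 99L, 50L)), tx, cfg0, seed = 1L)
  expect_equal(nrow(surv), 50L)
  expect_true(all(surv$duplicateCount == 1))
  expect_true(all(surv$insertStart == nStart & surv$insertLen == 100L))
  ## branching-process expectation (1 + eff)^cycles
  cfg9 <- LibraryConfig(pcrEfficiency = 0.9, pcrCycles = 20L, seed = 1L)
  amp <- nestedPcrSizeSelect(mk(rep(nStart + 99L, 1000L)), tx, cfg9, seed = 2L)
  expect_lt(abs(mean(amp$duplicateCount) / 1.9^20 - 1), 0.05)
})

test_that("reads mirror the insert with adapter read-through", {
  toy <- toyRef()
  pool <- samplePreset("nci-h660", toy$models, toy$genome)
  tx <- setNames(pool$sequence, pool$id)
  mols <- data.table::data.table(
    transcript = "TMPRSS2.wt", spanStart = 1L,
    end = c(235L, 115L), insertStart = 36L,
    insertLen = c(200L, 80L), duplicateCount = c(1, 1))
  cfg <- LibraryConfig(substitutionRate = 0, seed = 1L)
  pairs <- sequencePairs(mols, tx, cfg, seed = 1L)
  insert200 <- substr(tx[["TMPRSS2.wt"]], 36L, 235L)
  expect_identical(pairs$r1[1], substr(insert200, 1, 150))
  expect_true(startsWith(pairs$r1[1], "GGAGGCGGAGGGCGAGGG"))
  ## 80-nt insert: R1 reads through the OTDDN adapter
  expect_identical(substr(pairs$r1[2], 81, 102), "AGATCGGAAGAGCACACGTCTG")
  ## R2 is the reverse complement from the termination base
  insert80 <- substr(tx[["TMPRSS2.wt"]], 36L, 115L)
  expect_identical(substr(pairs$r2[2], 1, 80),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(insert80))))
})

test_that("substitution errors appear at the configured rate", {
  mols <- data.table::data.table(
    transcript = "t", spanStart = 1L, end = 200L, insertStart = 1L,
    insertLen = 200L, duplicateCount = 400)
  tx <- c(t = strrep("ACGT", 50))
  cfg <- LibraryConfig(substitutionRate = 0.01, seed = 1L)
  pairs <- sequencePairs(mols, tx, cfg, seed = 5L)
  clean <- sequencePairs(mols, tx, LibraryConfig(substitutionRate = 0),
                         seed = 5L)
  nBases <- sum(nchar(pairs$r1))
  mm <- sum(vapply(seq_len(nrow(pairs)), function(i)
    sum(charToRaw(pairs$r1[i]) != charToRaw(clean$r1[i])), integer(1)))
  se <- sqrt(0.01 * 0.99 / nBases)
  expect_lt(abs(mm / nBases - 0.01), 3 * se)
  ## error positions carry the reduced quality
  i <- which(pairs$r1 != clean$r1)[1]
  at <- which(charToRaw(pairs$r1[i]) != charToRaw(clean$r1[i]))[1]
  expect_equal(substr(pairs$q1[i], at, at), ",")
})

test_that("simulated libraries are deterministic and conserve molecules", {
  toy <- toyRef()
  pool <- samplePreset("nci-h660", toy$models, toy$genome)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  cfg <- LibraryConfig(depth = 2000L, seed = 99L)
  o1 <- simulateLibrary(pool, cfg, d1, nMolecules = 50000L)
  o2 <- simulateLibrary(pool, cfg, d2, nMolecules = 50000L)
  expect_identical(readLines(o1$r1[1]), readLines(o2$r1[1]))
  expect_identical(readLines(o1$r2[2]), readLines(o2$r2[2]))
  ## conservation: every pair maps to exactly one truth molecule, and the
  ## depth normalisation emits exactly `depth` pairs per replicate
  tp <- data.table::fread(o1$truthPairs)
  expect_equal(nrow(tp[replicate == 1]), 2000L)
  expect_equal(anyDuplicated(tp$pairId), 0L)
  fq <- readFastq(o1$r1[1])
  expect_identical(sort(fq$id), sort(tp[replicate == 1]$pairId))
})

test_that("only primer-bearing transcripts yield reads", {
  toy <- toyRef()
  pool <- samplePreset("lncap", toy$models, toy$genome)
  cfg <- LibraryConfig(depth = 1000L, substitutionRate = 0, seed = 5L)
  out <- simulateLibrary(pool, cfg, file.path(tempdir(), "enr"),
                         nMolecules = 30000L)
  tp <- data.table::fread(out$truthPairs)
  expect_equal(nrow(tp[class == "housekeeping"]), 0L)
  expect_equal(nrow(tp[class == "fusion"]), 0L)
  fq <- readFastq(out$r1[1])
  expect_true(all(startsWith(fq$seq, "GGAGGCGGAGGGCGAGGG")))
})

test_that("fusion-positive preset leaves molecular truth for every isoform", {
  sim <- toySim()
  tm <- data.table::fread(sim$truthMolecules)
  fus <- tm[class == "fusion" & replicate == 1]
  expect_setequal(fus$isoform,
                  c("T1-E4", "T2-E4", "T1-EIIIa", "T2-E5", "T1-E5"))
  expect_true(all(fus$molecules >= 1))
  hk <- tm[class == "housekeeping" & replicate == 1]$molecules
  expect_lt(abs(hk / mean(fus$molecules) - 1000) / 1000, 0.2)
})

test_that("raising the terminator ratio shortens inserts", {
  toy <- toyRef()
  pool <- samplePreset("nci-h660", toy$models, toy$genome)
  meanInsert <- vapply(c(0.05, 0.1, 0.2), function(r) {
    mix <- NucleotideMix(dCTP = 1 - r, dTTP = 1 - r, ddC_ON = r, ddU_ON = r)
    cfg <- LibraryConfig(mix = mix, depth = 3000L, seed = 21L)
    out <- simulateLibrary(pool, cfg,
                           file.path(tempdir(), paste0("ratio", r * 100)),
                           nMolecules = 50000L)
    tp <- data.table::fread(out$truthPairs)
    mean(tp$insertLen)
  }, numeric(1))
  expect_true(all(diff(meanInsert) < 0))
})

test_that("fastq io round-trips and validates", {
  dt <- data.table::data.table(pairId = c("a", "b"), r1 = c("ACGT", "GGTT"),
                               r2 = c("TTAA", "CCGG"), q1 = c("IIII", "IIII"),
                               q2 = c("IIII", "IIII"))
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq")
  writeFastq(dt, f1, f2)
  back <- readFastq(f1)
  expect_identical(back$seq, dt$r1)
  bad <- tempfile(); writeLines(c("@x", "ACGT", "+"), bad)
  expect_error(readFastq(bad), "truncated")
  bad2 <- tempfile(); writeLines(c("x", "ACGT", "+", "IIII"), bad2)
  expect_error(readFastq(bad2), "record 1")
})
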