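## Generative simulator of the FTAS-seq library chemistry: RNA sampling and
## degradation, reverse transcription, terminator-assisted second-strand
## synthesis from the outer anchor primer, nested indexing PCR with size
## selection, and paired-end sequencing.

#' Sample RNA molecules, degrade, and reverse transcribe
#'
#' Molecules are drawn multinomially from the transcript pool by abundance.
#' Each RNA is fragmented by independent per-phosphodiester-bond breaks at
#' `degradationRate`; each fragment is then reverse transcribed from either
#' a uniform random internal position (random priming, fraction
#' `randomPrimingFraction`) or its 3' end (oligo-dT), yielding a cDNA span
#' covering the fragment from its 5' end up to the priming position. Only
#' spans that cover the full outer-primer site can later serve as extension
#' templates; that coverage is decided downstream, not here.
#'
#' @param pool data.frame with columns `id`, `sequence`, `abundance`
#'   (positive weights).
#' @param degradationRate per-bond break probability in `[0, 1)`.
#' @param nMolecules number of RNA molecules to sample.
#' @param seed integer seed.
#' @param randomPrimingFraction fraction of fragments primed internally.
#' @return List with `spans` (data.table: `molecule`, `transcript`,
#'   `start`, `end` in 1-based transcript coordinates) and `counts`
#'   (data.table: `transcript`, `molecules` sampled), the truth record of
#'   the sampling step.
#' @export
degradeAndReverseTranscribe <- function(pool, degradationRate = 0,
                                        nMolecules, seed = 1L,
                                        randomPrimingFraction = 0.5) {
  if (nrow(pool) == 0L) stop("transcript pool is empty")
  stopifnot(all(pool$abundance > 0), nMolecules > 0)
  withSeed(seed, {
    counts <- as.vector(rmultinom(1L, nMolecules, prob = pool$abundance))
    lens <- nchar(pool$sequence)
    frag <- vector("list", nrow(pool))
    molOffset <- 0L
    for (i in seq_len(nrow(pool))) {
      n <- counts[i]
      if (n == 0L) next
      L <- lens[i]
      if (degradationRate > 0 && L > 1L) {
        nBonds <- as.numeric(n) * (L - 1L)
        nBreaks <- rbinom(1L, nBonds, degradationRate)
        idx <- if (nBreaks > 0L) sort(sample(nBonds, nBreaks)) else numeric(0)
        mol <- as.integer((idx - 1) %/% (L - 1L)) + 1L
        bond <- as.integer((idx - 1) %% (L - 1L)) + 1L  # break after base `bond`
        dt <- data.table(mol = c(mol, seq_len(n)),
                         cut = c(bond, rep(L, n)))     # sentinel: molecule end
        setorder(dt, mol, cut)
        fragEnd <- dt$cut
        fragStart <- c(1L, fragEnd[-length(fragEnd)] + 1L)
        newMol <- c(TRUE, dt$mol[-1L] != dt$mol[-length(dt$mol)])
        fragStart[newMol] <- 1L
        frag[[i]] <- data.table(molecule = molOffset + dt$mol,
                                transcript = pool$id[i],
                                fragStart = fragStart, fragEnd = fragEnd)
      } else {
        frag[[i]] <- data.table(molecule = molOffset + seq_len(n),
                                transcript = pool$id[i],
                                fragStart = 1L, fragEnd = L)
      }
      molOffset <- molOffset + n
    }
    frags <- rbindlist(frag)
    countsDt <- data.table(transcript = pool$id, molecules = counts)
    if (nrow(frags) == 0L)
      return(list(spans = data.table(molecule = integer(0),
                                     transcript = character(0),
                                     start = integer(0), end = integer(0)),
                  counts = countsDt))
    internal <- runif(nrow(frags)) < randomPrimingFraction
    prime <- frags$fragEnd
    if (any(internal)) {
      w <- frags$fragEnd[internal] - frags$fragStart[internal] + 1L
      prime[internal] <- frags$fragStart[internal] +
        as.integer(floor(runif(sum(internal)) * w))
    }
    list(spans = data.table(molecule = frags$molecule,
                            transcript = frags$transcript,
                            start = frags$fragStart, end = prime),
         counts = countsDt)
  })
}

#' Terminator-assisted primer extension
#'
#' Simulates linear second-strand synthesis: per cycle, one nascent strand
#' per template walks 3'-ward from the primer; each incorporated C
#' terminates with probability `p_term_C`, each T with `p_term_T`
#' (concentration-proportional competition, see
#' [terminationProbs()]); A and G never terminate. Synthesis stops at
#' termination or at the template end. Templates are given in mRNA sense;
#' the nascent strand copies them, so terminator-terminated strands always
#' end on a pyrimidine. The OTDDN adapter is conceptually tethered at the
#' terminal base and is appended at sequencing.
#'
#' @param template mRNA-sense template sequence (one cDNA span).
#' @param primer primer sequence; must occur exactly in the template. A
#'   template without the primer site returns an empty record set: that
#'   molecule is simply not amplifiable, which is the mechanism of target
#'   enrichment.
#' @param mix A [NucleotideMix-class].
#' @param cycles number of linear extension cycles.
#' @param seed integer seed.
#' @return data.table with one row per nascent strand: `cycle`, `start`
#'   (primer 5' position in the template), `end` (position of the last
#'   incorporated base), `terminated` (by terminator, vs template end),
#'   `nPyr` (pyrimidines incorporated), `terminalBase`.
#' @export
extendWithTerminators <- function(template, primer, mix = NucleotideMix(),
                                  cycles = 15L, seed = 1L) {
  pStart <- firstMatch(primer, template)
  if (is.na(pStart)) {
    return(data.table(cycle = integer(0), start = integer(0),
                      end = integer(0), terminated = logical(0),
                      nPyr = integer(0), terminalBase = character(0)))
  }
  pEnd <- pStart + nchar(primer) - 1L
  L <- nchar(template)
  res <- withSeed(seed, extendEngine(
    template, pEnd, limits = rep(L, cycles), mix = mix))
  data.table(cycle = seq_len(cycles), start = pStart, end = res$end,
             terminated = res$terminated, nPyr = res$nPyr,
             terminalBase = res$terminalBase)
}

## Vectorised extension core: one template sequence, many walks that each
## start at `primerEnd + 1` and are truncated at their own `limit`.
## Termination index is drawn by inverse CDF over the per-pyrimidine
## termination probabilities, which is exact for independent per-position
## Bernoulli termination.
extendEngine <- function(template, primerEnd, limits, mix) {
  p <- terminationProbs(mix)
  bases <- strsplit(substr(template, primerEnd + 1L, nchar(template)),
                    "")[[1]]
  isPyr <- bases %in% c("C", "T")
  pyrPos <- primerEnd + which(isPyr)
  q <- ifelse(bases[isPyr] == "C", p[["C"]], p[["T"]])
  n <- length(limits)
  if (length(pyrPos) == 0L) {
    return(list(end = pmin(limits, nchar(template)), nPyr = rep(0L, n),
                terminated = rep(FALSE, n),
                terminalBase = rep(NA_character_, n)))
  }
  cumP <- 1 - cumprod(1 - q)            # P(terminated at or before j-th pyr)
  k <- findInterval(runif(n), cumP) + 1L
  nAvail <- findInterval(limits, pyrPos)
  terminated <- k <= nAvail
  end <- ifelse(terminated, pyrPos[pmin(k, length(pyrPos))], limits)
  nPyr <- pmin(k, nAvail)
  terminalBase <- rep(NA_character_, n)
  terminalBase[terminated] <- bases[end[terminated] - primerEnd]
  list(end = as.integer(end), nPyr = as.integer(nPyr),
       terminated = terminated, terminalBase = terminalBase)
}

#' Nested indexing PCR and size selection
#'
#' Molecules lacking the nested-primer site downstream of their 5' end are
#' dropped (nested specificity); survivors are re-anchored so the insert
#' begins at the nested primer's 5' position. Amplification is a per-cycle
#' Galton-Watson branching process with duplication probability
#' `pcrEfficiency` over `pcrCycles`, recorded as `duplicateCount`. Inserts
#' outside the size-selection window are dropped.
#'
#' @param molecules data.table of extension products with columns
#'   `transcript`, `spanStart` (cDNA span 5' end) and `end` (termination
#'   position), plus any provenance columns, all in transcript coordinates.
#' @param transcripts named character vector of transcript sequences.
#' @param cfg A [LibraryConfig-class].
#' @param seed integer seed.
#' @return The surviving molecules with `insertStart`, `insertLen` and
#'   `duplicateCount` columns added.
#' @export
nestedPcrSizeSelect <- function(molecules, transcripts, cfg, seed = 1L) {
  nStart <- vapply(transcripts, function(s)
    firstMatch(cfg@nestedPrimer, s), integer(1))
  nEnd <- nStart + nchar(cfg@nestedPrimer) - 1L
  ns <- nStart[molecules$transcript]
  ne <- nEnd[molecules$transcript]
  keep <- !is.na(ns) & molecules$spanStart <= ns & molecules$end >= ne
  out <- molecules[keep]
  insertStart <- ns[keep]
  insertLen <- out$end - insertStart + 1L
  inWindow <- insertLen >= cfg@sizeWindow[1] & insertLen <= cfg@sizeWindow[2]
  out <- out[inWindow]
  out[, `:=`(insertStart = insertStart[inWindow],
             insertLen = insertLen[inWindow])]
  n <- nrow(out)
  dup <- rep(1, n)
  if (n > 0L && cfg@pcrCycles > 0L && cfg@pcrEfficiency > 0) {
    dup <- withSeed(seed, {
      x <- rep(1, n)
      for (cyc in seq_len(cfg@pcrCycles))
        x <- x + rbinom(n, x, cfg@pcrEfficiency)
      x
    })
  }
  out[, duplicateCount := as.numeric(dup)]
  out[]
}

#' Sequence molecules into paired-end reads
#'
#' R1 reads the insert from the nested-primer 5' end; when the insert is
#' shorter than the read it runs into the OTDDN adapter and then fixed
#' post-adapter context. R2 reads the reverse complement from the
#' termination base back toward the primer, running into the reverse
#' complement of the i5 adapter on short inserts. Each molecule is emitted
#' `duplicateCount` times with iid substitution errors at
#' `substitutionRate`; qualities are constant Q30 except at error
#' positions, which get Q11.
#'
#' @param molecules output of [nestedPcrSizeSelect()].
#' @param transcripts named character vector of transcript sequences.
#' @param cfg A [LibraryConfig-class].
#' @param seed integer seed.
#' @param replicate replicate number recorded in pair ids.
#' @return data.table with `pairId`, `r1`, `r2`, `q1`, `q2` and provenance
#'   columns (`transcript`, `insertStart`, `insertLen`, `end`, `dupIndex`).
#' @export
sequencePairs <- function(molecules, transcripts, cfg, seed = 1L,
                          replicate = 1L) {
  if (cfg@readLength <= 0L) stop("readLength must be positive")
  L <- cfg@readLength
  if (nrow(molecules) == 0L) {
    return(data.table(pairId = character(0), r1 = character(0),
                      r2 = character(0), q1 = character(0),
                      q2 = character(0)))
  }
  insert <- substr(transcripts[molecules$transcript],
                   molecules$insertStart, molecules$end)
  pad <- strrep("A", L)
  r1full <- substr(paste0(insert, cfg@otddnAdapter, FTAS_R1_POST_ADAPTER, pad),
                   1L, L)
  r2full <- substr(paste0(revComp(insert), FTAS_R2_ADAPTER, pad), 1L, L)
  dup <- as.integer(molecules$duplicateCount)
  idx <- rep(seq_len(nrow(molecules)), dup)
  dupIndex <- sequence(dup)
  r1 <- r1full[idx]; r2 <- r2full[idx]
  withSeed(seed, {
    r1e <- injectErrors(r1, cfg@substitutionRate)
    r2e <- injectErrors(r2, cfg@substitutionRate)
    if (cfg@indelRate > 0) {
      r1e <- injectIndels(r1e$reads, r1e$qual, cfg@indelRate, L)
      r2e <- injectIndels(r2e$reads, r2e$qual, cfg@indelRate, L)
    }
    out <- molecules[idx, .(transcript, insertStart, insertLen, end)]
    out[, `:=`(pairId = sprintf("ftas:%d:%07d", replicate, seq_along(idx)),
               dupIndex = dupIndex, r1 = r1e$reads, r2 = r2e$reads,
               q1 = r1e$qual, q2 = r2e$qual)]
    out[]
  })
}

## iid substitution errors; returns reads plus quality strings (Q30 base,
## Q11 at error positions).
injectErrors <- function(reads, rate) {
  n <- length(reads)
  L <- nchar(reads[1])
  qual <- rep(strrep("?", L), n)        # '?' = Q30
  if (rate > 0 && n > 0L) {
    total <- as.numeric(n) * L
    nErr <- rbinom(1L, total, rate)
    if (nErr > 0L) {
      at <- sample(total, nErr)
      rd <- as.integer((at - 1) %/% L) + 1L
      pos <- as.integer((at - 1) %% L) + 1L
      alphabet <- c("A", "C", "G", "T")
      cur <- substr(reads[rd], pos, pos)
      shift <- sample.int(3L, nErr, replace = TRUE)
      newBase <- alphabet[((match(cur, alphabet) - 1L + shift) %% 4L) + 1L]
      ## several errors can hit one read: apply in rounds so vectorised
      ## substr<- never writes twice to the same element in one pass
      o <- order(rd)
      rd <- rd[o]; pos <- pos[o]; newBase <- newBase[o]
      rank <- sequence(rle(rd)$lengths)
      for (r in seq_len(max(rank))) {
        s <- rank == r
        x <- reads[rd[s]]
        substr(x, pos[s], pos[s]) <- newBase[s]
        reads[rd[s]] <- x
        xq <- qual[rd[s]]
        substr(xq, pos[s], pos[s]) <- ","   # ',' = Q11
        qual[rd[s]] <- xq
      }
    }
  }
  list(reads = reads, qual = qual)
}

## Rare single-base insertions/deletions; reads re-padded to length L.
injectIndels <- function(reads, qual, rate, L) {
  n <- length(reads)
  hit <- which(runif(n) < rate * L)
  for (i in hit) {
    pos <- sample.int(L, 1L)
    if (runif(1) < 0.5) {               # deletion
      reads[i] <- substr(paste0(substr(reads[i], 1L, pos - 1L),
                                substr(reads[i], pos + 1L, L), "A"), 1L, L)
    } else {                            # insertion
      ins <- sample(c("A", "C", "G", "T"), 1L)
      reads[i] <- substr(paste0(substr(reads[i], 1L, pos - 1L), ins,
                                substr(reads[i], pos, L)), 1L, L)
    }
  }
  list(reads = reads, qual = qual)
}

#' Write paired reads as 4-line FASTQ
#'
#' @param pairs data.table from [sequencePairs()].
#' @param r1Path,r2Path output paths; a `.gz` suffix gzip-compresses.
#' @return (invisibly) the two paths.
#' @export
writeFastq <- function(pairs, r1Path, r2Path) {
  writeOne <- function(ids, seqs, quals, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    if (length(ids))
      writeLines(as.vector(rbind(paste0("@", ids), seqs,
                                 rep("+", length(ids)), quals)), con)
  }
  writeOne(pairs$pairId, pairs$r1, pairs$q1, r1Path)
  writeOne(pairs$pairId, pairs$r2, pairs$q2, r2Path)
  invisible(c(r1Path, r2Path))
}

#' Read 4-line FASTQ into a data.table
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.table with `id`, `seq`, `qual`.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): record ",
         length(lines) %/% 4L + 1L, " is truncated")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.table(id = character(0), seq = character(0),
                      qual = character(0)))
  idx <- seq_len(n)
  hdr <- lines[(idx - 1L) * 4L + 1L]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ (", path, "): record ", bad[1], " lacks '@' header")
  data.table(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = lines[(idx - 1L) * 4L + 2L],
             qual = lines[(idx - 1L) * 4L + 4L])
}

#' Simulate a full FTAS-seq experiment
#'
#' Runs the whole chain (sampling/degradation/reverse transcription,
#' terminator-assisted extension, nested PCR with size selection,
#' sequencing) for `cfg@replicates` independent technical replicates with
#' sub-seeds derived from the master seed. Sequencing depth is normalised
#' to `cfg@depth` pairs per replicate by multinomial resampling of the PCR
#' duplicate counts, so the emitted pairs are a depth-`cfg@depth` draw from
#' the amplified library; every pair still maps to exactly one truth
#' molecule.
#'
#' @param sampleConfig data.frame describing the transcript pool: columns
#'   `id`, `sequence`, `abundance`, `class` (`"fusion"`, `"wildtype"`, or
#'   `"housekeeping"`) and `isoform` (isoform name, or `NA`). See
#'   [samplePreset()].
#' @param cfg A [LibraryConfig-class].
#' @param outDir output directory; created if needed.
#' @param nMolecules RNA molecules sampled per replicate.
#' @return (invisibly) list with per-replicate FASTQ paths, the truth pair
#'   TSV (`truth_pairs.tsv`), and the truth molecule-count TSV
#'   (`truth_molecules.tsv`).
#' @export
simulateLibrary <- function(sampleConfig, cfg = LibraryConfig(), outDir,
                            nMolecules = 100000L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  transcripts <- setNames(sampleConfig$sequence, sampleConfig$id)
  meta <- sampleConfig[, c("id", "class", "isoform")]
  r1Paths <- character(0); r2Paths <- character(0)
  truthPairs <- list(); truthMols <- list()
  for (rep in seq_len(cfg@replicates)) {
    rt <- degradeAndReverseTranscribe(
      sampleConfig, cfg@degradationRate, nMolecules,
      seed = deriveSeed(cfg@seed, 1L, rep),
      randomPrimingFraction = cfg@randomPrimingFraction)
    cnt <- merge(rt$counts, meta, by.x = "transcript", by.y = "id",
                 sort = FALSE)
    cnt[, replicate := rep]
    truthMols[[rep]] <- cnt

    ## extension only on templates that carry the full outer-primer site
    oStart <- vapply(transcripts, function(s)
      firstMatch(cfg@outerPrimer, s), integer(1))
    oEnd <- oStart + nchar(cfg@outerPrimer) - 1L
    sp <- rt$spans
    os <- oStart[sp$transcript]; oe <- oEnd[sp$transcript]
    sp <- sp[which(!is.na(os) & sp$start <= os & sp$end >= oe)]
    mols <- extendTemplates(sp, transcripts, cfg,
                            seed = deriveSeed(cfg@seed, 2L, rep))
    mols <- nestedPcrSizeSelect(mols, transcripts, cfg,
                                seed = deriveSeed(cfg@seed, 3L, rep))
    mols <- downsampleToDepth(mols, cfg@depth,
                              seed = deriveSeed(cfg@seed, 4L, rep))
    pairs <- sequencePairs(mols, transcripts, cfg,
                           seed = deriveSeed(cfg@seed, 5L, rep),
                           replicate = rep)
    r1 <- file.path(outDir, sprintf("rep%d_R1.fastq", rep))
    r2 <- file.path(outDir, sprintf("rep%d_R2.fastq", rep))
    writeFastq(pairs, r1, r2)
    r1Paths <- c(r1Paths, r1); r2Paths <- c(r2Paths, r2)
    tp <- if (nrow(pairs)) {
      merge(pairs[, .(pairId, transcript, insertStart, insertLen, end,
                      dupIndex)],
            meta, by.x = "transcript", by.y = "id", sort = FALSE)
    } else {
      data.table(pairId = character(0), transcript = character(0),
                 insertStart = integer(0), insertLen = integer(0),
                 end = integer(0), dupIndex = integer(0),
                 class = character(0), isoform = character(0))
    }
    tp[, `:=`(replicate = rep,
              terminationOffset = if (.N) end - insertStart else integer(0))]
    truthPairs[[rep]] <- tp
  }
  tpAll <- rbindlist(truthPairs)
  setorder(tpAll, replicate, pairId)
  pairsPath <- file.path(outDir, "truth_pairs.tsv")
  molsPath <- file.path(outDir, "truth_molecules.tsv")
  write.table(tpAll[, .(replicate, pairId, transcript, class, isoform,
                        terminationOffset, insertLen, dupIndex)],
              pairsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rbindlist(truthMols)[, .(replicate, transcript, class,
                                       isoform, molecules)],
              molsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(r1 = r1Paths, r2 = r2Paths, truthPairs = pairsPath,
                 truthMolecules = molsPath))
}

## Batch terminator-assisted extension over cDNA spans (transcript
## coordinates), `cfg@extensionCycles` nascent strands per template.
extendTemplates <- function(spans, transcripts, cfg, seed = 1L) {
  if (nrow(spans) == 0L) {
    return(data.table(transcript = character(0), molecule = integer(0),
                      spanStart = integer(0), cycle = integer(0),
                      end = integer(0), terminated = logical(0),
                      nPyr = integer(0)))
  }
  cyc <- cfg@extensionCycles
  oEndOf <- vapply(transcripts, function(s) {
    m <- firstMatch(cfg@outerPrimer, s)
    if (is.na(m)) NA_integer_ else m + nchar(cfg@outerPrimer) - 1L
  }, integer(1))
  withSeed(seed, {
    out <- lapply(unique(spans$transcript), function(tx) {
      sub <- spans[spans$transcript == tx]
      limits <- rep(sub$end, each = cyc)
      res <- extendEngine(transcripts[[tx]], oEndOf[[tx]], limits, cfg@mix)
      data.table(
        transcript = tx, molecule = rep(sub$molecule, each = cyc),
        spanStart = rep(sub$start, each = cyc),
        cycle = rep(seq_len(cyc), nrow(sub)), end = res$end,
        terminated = res$terminated, nPyr = res$nPyr)
    })
    rbindlist(out)
  })
}

## Multinomial resampling of PCR duplicate counts to a fixed sequencing
## depth; molecules drawn zero times are dropped.
downsampleToDepth <- function(mols, depth, seed = 1L) {
  if (nrow(mols) == 0L || depth <= 0L) return(mols[integer(0)])
  withSeed(seed, {
    newCount <- as.vector(rmultinom(1L, depth, prob = mols$duplicateCount))
    mols <- mols[newCount > 0L]
    mols[, duplicateCount := newCount[newCount > 0L]]
    mols[]
  })
}

#' Bundled cell-line-like sample presets
#'
#' `"nci-h660"`: the fusion-positive configuration — the five fusion
#' isoforms of the positive cell line (`T1-E4`, `T2-E4`, `T1-EIIIa`,
#' `T2-E5`, `T1-E5`) each at relative abundance 1, wild-type anchor
#' transcript at 5, and the housekeeping transcript at 1000, reproducing
#' the ~1000-fold excess of housekeeping over fusion transcript measured in
#' that line. `"lncap"`: the fusion-negative configuration — wild-type
#' anchor and housekeeping transcripts only.
#'
#' @param name `"nci-h660"` or `"lncap"`.
#' @param models toy gene models (see [makeToyReference()]).
#' @param genome toy genome ([Biostrings::DNAStringSet]).
#' @return data.frame suitable for [simulateLibrary()].
#' @export
samplePreset <- function(name = c("nci-h660", "lncap"), models, genome) {
  name <- match.arg(name)
  tm <- canonicalModel(models, "TMPRSS2")
  gapdh <- canonicalModel(models, "GAPDH")
  base <- data.frame(
    id = c("TMPRSS2.wt", "GAPDH.wt"),
    sequence = c(transcriptSeq(tm, genome), transcriptSeq(gapdh, genome)),
    abundance = c(5, 1000),
    class = c("wildtype", "housekeeping"),
    isoform = NA_character_, stringsAsFactors = FALSE)
  if (name == "lncap") return(base)
  isoforms <- c("T1-E4", "T2-E4", "T1-EIIIa", "T2-E5", "T1-E5")
  fus <- do.call(rbind, lapply(isoforms, function(nm) {
    defn <- toyFusion(models, nm)
    data.frame(id = paste0("fusion.", nm),
               sequence = buildFusionTranscript(defn, genome),
               abundance = 1, class = "fusion", isoform = nm,
               stringsAsFactors = FALSE)
  }))
  rbind(base, fus)
}
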