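## Adapter/quality trimming of read pairs. Semantics follow the stated
## processing rules: right-side adapter k-mer trimming with one mismatch
## allowed (seed k shortening toward a minimum k at the read end),
## right-side quality trimming, pair-equalising trim when a mate is
## adapter-trimmed, and pair discard on short length or ambiguous bases.

#' Trim a set of read pairs
#'
#' Vectorised trimming of paired reads. Adapter occurrences (any of
#' `cfg@adapters`) are searched as exact/1-mismatch k-mers of length
#' `adapterKmer`, shortening to `adapterMinKmer` at the read 3' end; the
#' read is cut at the earliest adapter start. Trailing bases with quality
#' below `qtrimThreshold` are removed. If a mate was adapter-trimmed, the
#' pair is trimmed to a common insert length. Pairs with a mate shorter
#' than `minLength`, or with more than `maxN` ambiguous bases, are
#' discarded with a reason.
#'
#' @param r1,r2 character vectors of read sequences.
#' @param q1,q2 matching quality strings (Phred+33).
#' @param cfg A [TrimConfig-class].
#' @return List: `r1`, `r2`, `q1`, `q2` (trimmed, kept pairs only), `keep`
#'   (logical over input pairs), `reason` (per discarded pair:
#'   `"too_short"` or `"too_many_N"`), and `insertComplete` (kept pairs:
#'   was either mate adapter-trimmed, implying the trimmed read spans the
#'   whole insert).
#' @export
trimPairs <- function(r1, r2, q1, q2, cfg = TrimConfig()) {
  if (length(r1) != length(r2))
    stop("r1 and r2 must have equal length")
  if (any(nchar(r1) != nchar(q1)) || any(nchar(r2) != nchar(q2)))
    stop("sequence/quality length mismatch")
  n <- length(r1)
  if (n == 0L) {
    return(list(r1 = character(0), r2 = character(0), q1 = character(0),
                q2 = character(0), keep = logical(0), reason = character(0)))
  }
  t1 <- trimMate(r1, q1, cfg)
  t2 <- trimMate(r2, q2, cfg)
  ## tpe/tbo semantics: an adapter hit on one mate implies the insert ends
  ## there for both; trim the pair to the shortest adapter-implied insert
  target <- pmin(ifelse(t1$adapterTrimmed, t1$len, .Machine$integer.max),
                 ifelse(t2$adapterTrimmed, t2$len, .Machine$integer.max))
  any_ad <- t1$adapterTrimmed | t2$adapterTrimmed
  len1 <- ifelse(any_ad, pmin(t1$len, target), t1$len)
  len2 <- ifelse(any_ad, pmin(t2$len, target), t2$len)
  nN <- countNUpTo(r1, len1) + countNUpTo(r2, len2)
  reason <- rep(NA_character_, n)
  reason[nN > cfg@maxN] <- "too_many_N"
  short <- len1 < cfg@minLength | len2 < cfg@minLength
  reason[short] <- "too_short"
  keep <- is.na(reason)
  list(r1 = substr(r1[keep], 1L, len1[keep]),
       r2 = substr(r2[keep], 1L, len2[keep]),
       q1 = substr(q1[keep], 1L, len1[keep]),
       q2 = substr(q2[keep], 1L, len2[keep]),
       keep = keep, reason = reason[!keep],
       insertComplete = any_ad[keep])
}

#' Trim a single read pair
#'
#' Single-pair convenience wrapper around [trimPairs()].
#' @inheritParams trimPairs
#' @return List with `r1`, `r2`, `q1`, `q2` (or `NULL`s when discarded) and
#'   `discarded`/`reason`.
#' @export
trimPair <- function(r1, r2, q1, q2, cfg = TrimConfig()) {
  res <- trimPairs(r1, r2, q1, q2, cfg)
  if (!res$keep) {
    list(r1 = NULL, r2 = NULL, q1 = NULL, q2 = NULL, discarded = TRUE,
         reason = res$reason)
  } else {
    list(r1 = res$r1, r2 = res$r2, q1 = res$q1, q2 = res$q2,
         discarded = FALSE, reason = NA_character_)
  }
}

## Per-mate trimming: returns post-trim length and whether an adapter
## was involved.
trimMate <- function(reads, quals, cfg) {
  n <- length(reads)
  len <- nchar(reads)
  W <- max(len)
  adapterAt <- rep(NA_integer_, n)
  rm_ <- rawMatrix(reads, W)
  ## internal (full-k) adapter matches: exact search first (vectorised,
  ## compiled), then a sliding raw-byte comparison with the allowed
  ## mismatch budget for the few reads with an error in the adapter region
  for (ad in cfg@adapters) {
    k <- min(cfg@adapterKmer, nchar(ad))
    seedStr <- substr(ad, 1L, k)
    hit <- regexpr(seedStr, reads, fixed = TRUE)
    found <- hit > 0L
    adapterAt[found] <- pmin(adapterAt[found], hit[found], na.rm = TRUE)
    if (cfg@adapterMaxMismatch > 0L) {
      cand <- which(!found & len >= k)
      if (length(cand)) {
        adRaw <- charToRaw(seedStr)
        best <- rep(NA_integer_, length(cand))
        for (s in seq_len(W - k + 1L)) {
          todo <- which(is.na(best) & len[cand] >= s + k - 1L)
          if (!length(todo)) break
          mm <- integer(length(todo))
          for (j in seq_len(k))
            mm <- mm + (rm_[cbind(cand[todo], s + j - 1L)] != adRaw[j])
          ok <- mm <= cfg@adapterMaxMismatch
          best[todo[ok]] <- s
        }
        got <- !is.na(best)
        adapterAt[cand[got]] <- pmin(adapterAt[cand[got]], best[got],
                                     na.rm = TRUE)
      }
    }
  }
  ## partial adapter at the read 3' end (length adapterMinKmer .. k-1)
  for (ad in cfg@adapters) {
    k <- min(cfg@adapterKmer, nchar(ad))
    adRaw <- charToRaw(ad)
    for (l in seq(k - 1L, cfg@adapterMinKmer)) {
      cand <- which(len >= l & (is.na(adapterAt) | adapterAt > len - l + 1L))
      if (!length(cand)) next
      mm <- integer(length(cand))
      for (j in seq_len(l)) {
        col <- len[cand] - l + j
        mm <- mm + (rm_[cbind(cand, col)] != adRaw[j])
      }
      hit <- mm <= cfg@adapterMaxMismatch
      adapterAt[cand[hit]] <- len[cand[hit]] - l + 1L
    }
  }
  lenAd <- ifelse(is.na(adapterAt), len, adapterAt - 1L)
  ## right-side quality trim: cut the trailing run below threshold
  qm <- rawMatrix(quals, W)
  thr <- as.raw(33L + cfg@qtrimThreshold)
  lastGood <- integer(n)
  colIdx <- seq_len(W)
  for (j in colIdx) {
    good <- qm[, j] >= thr & j <= lenAd
    lastGood[good] <- j
  }
  newLen <- pmin(lenAd, lastGood)
  list(len = as.integer(newLen), adapterTrimmed = !is.na(adapterAt))
}

## Number of 'N' bases within the first `len` characters of each read.
countNUpTo <- function(reads, len) {
  counts <- integer(length(reads))
  hasN <- grepl("N", reads, fixed = TRUE)
  if (any(hasN)) {
    counts[hasN] <- vapply(which(hasN), function(i) {
      sum(charToRaw(substr(reads[i], 1L, len[i])) == charToRaw("N"))
    }, integer(1))
  }
  counts
}
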