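## Internal helpers shared across modules.

## Derive a reproducible sub-seed from a master seed. Kept below 2^31 so the
## result is always a valid R integer seed.
deriveSeed <- function(seed, stage, replicate = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 7919 + stage * 104729 + replicate * 7907) %%
               2147483629)
}

## Run an expression under a local RNG state seeded with `seed`; the caller's
## RNG stream is left untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## Random DNA of length n from the current RNG stream.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Pack a character vector of reads into a raw byte matrix (one row per
## read, padded with spaces to `width`). Byte-level comparison against
## reference bytes is the workhorse of the vectorised trimming / mapping
## engine: a 2e5 x 150 raw matrix is ~30 MB and compares in milliseconds.
rawMatrix <- function(x, width) {
  n <- length(x)
  if (n == 0L) return(matrix(raw(0), nrow = 0L, ncol = width))
  x <- substr(x, 1L, width)
  padded <- sprintf(paste0("%-", width, "s"), x)
  matrix(charToRaw(paste(padded, collapse = "")),
         nrow = n, ncol = width, byrow = TRUE)
}

## Count mismatches between the first `len` characters of two strings.
countMismatches <- function(a, b, len = min(nchar(a), nchar(b))) {
  if (len == 0L) return(0L)
  sum(charToRaw(substr(a, 1L, len)) != charToRaw(substr(b, 1L, len)))
}

## First occurrence (1-based) of `pattern` in `subject` (exact); NA if absent.
firstMatch <- function(pattern, subject) {
  m <- regexpr(pattern, subject, fixed = TRUE)
  if (m[1] == -1L) NA_integer_ else as.integer(m[1])
}

## Roman numeral (upper case) for an intron index.
romanIndex <- function(i) as.character(as.roman(i))

`%||%` <- function(a, b) if (is.null(a)) b else a
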