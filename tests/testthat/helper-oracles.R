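# Independent reference implementations used to validate the package's
# optimized code paths. These deliberately avoid the package's internal
# machinery (complex prefix sums, C++ parsing): the LZ76 oracle parses
# literally by testing copyability with fixed-string search, and the
# brute-force scanner tests base-level complementarity directly.

# Literal LZ76 exhaustive-history parser: a phrase extends while the
# current extension occurs (self-overlap allowed) in the preceding
# sequence; the first non-copyable extension closes the phrase; a final
# still-copyable run counts as one phrase.
lz76_oracle_phrases <- function(s) {
  n <- nchar(s)
  i <- 1L
  c <- 0L
  while (i <= n) {
    m <- 1L
    repeat {
      if (i + m - 1L > n) {        # tail still copyable at end of string
        return(c + 1L)
      }
      ext <- substr(s, i, i + m - 1L)
      hist <- substr(s, 1L, i + m - 2L)
      if (!grepl(ext, hist, fixed = TRUE)) break
      m <- m + 1L
    }
    c <- c + 1L
    i <- i + m
  }
  c
}

lz_oracle <- function(s) {
  n <- nchar(s)
  lz76_oracle_phrases(s) * (log(n) / log(4)) / n
}

# Brute-force structural MITE scanner: for every (start, span) directly
# counts non-complementary TIR base pairs and searches the longest exact
# direct repeat. Returns (start, end, tsd) rows for comparison with
# scan_chromosome.
brute_scan_oracle <- function(bases, cfg) {
  n <- nchar(bases)
  w <- cfg$tir_len
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[ch]
  comp[is.na(comp)] <- "?"
  bad <- !(ch %in% c("A", "C", "G", "T"))
  badcum <- c(0L, cumsum(bad))
  rows <- list()
  for (d in seq.int(cfg$min_len, min(cfg$max_len, n))) {
    m <- n - d + 1L
    if (m < 1L) break
    i <- seq_len(m)
    mism <- integer(m)
    for (k in seq_len(w)) {
      # left arm position k (abs i+k-1) pairs with abs position i+d-k
      mism <- mism + (comp[i + k - 1L] != ch[i + d - k])
    }
    ok <- mism <= cfg$max_tir_mismatch & (badcum[i + d] - badcum[i]) == 0L
    for (s in i[ok]) {
      e <- s + d - 1L
      tsd <- NA_character_
      for (L in seq.int(cfg$tsd_max, cfg$tsd_min)) {
        if (s - L < 1L || e + L > n) next
        lf <- substr(bases, s - L, s - 1L)
        if (grepl("[^ACGT]", lf)) next
        if (lf == substr(bases, e + 1L, e + L)) {
          tsd <- lf
          break
        }
      }
      if (!is.na(tsd)) {
        rows[[length(rows) + 1L]] <- data.frame(start = s, end = e, tsd = tsd,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      tsd = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# canonical key for set comparison of candidate tables
cand_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$start, df$end, df$tsd, sep = ":"))
}

# per-base complex score, recomputed from the mapping definition
complex_score <- function(s) {
  lut <- c(A = 1 + 0i, T = -1 + 0i, C = 0 + 1i, G = 0 - 1i)
  sum(lut[strsplit(s, "", fixed = TRUE)[[1]]])
}

l1_norm <- function(z) abs(Re(z)) + abs(Im(z))

# Needleman-Wunsch with free end gaps, score only (match/mismatch/linear
# gap): reference for the alignment scores behind clustering and flank
# comparison.
nw_overlap_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  prev <- numeric(m + 1L)                 # free leading gaps
  best_last_col <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- 0                           # free leading gaps in B
    for (j in seq_len(m)) {
      sc <- if (A[i] == B[j]) match else mismatch
      cur[j + 1L] <- max(prev[j] + sc, prev[j + 1L] - gap, cur[j] - gap)
    }
    best_last_col <- max(best_last_col, cur[m + 1L])
    prev <- cur
  }
  # free trailing gaps: maximize over the last row and the last column
  max(best_last_col, max(prev))
}

# Smith-Waterman local alignment score with gap open/extend, reference for
# representative selection scoring.
sw_local_score <- function(a, b, match = 2, mismatch = -3,
                           gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - gap_open - gap_ext,
                               E[i + 1L, j] - gap_ext)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - gap_open - gap_ext,
                               F[i, j + 1L] - gap_ext)
      sc <- if (A[i] == B[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + sc,
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# draw k 50-mers whose pairwise alignment matches all stay below `bar`
# (random pairs cross the default bar ~7% of the time, so fixtures that
# must be flank-divergent are rejection-sampled)
draw_divergent_flanks <- function(k, bar = 25L) {
  out <- character(0)
  while (length(out) < k) {
    cand <- random_seq(50)
    if (all(vapply(out, function(o) mitescan::flank_matches(o, cand) < bar,
                   logical(1)))) {
      out <- c(out, cand)
    }
  }
  out
}
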