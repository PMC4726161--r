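#' @useDynLib mitescan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# integer codes A=1, C=2, G=3, T=4, anything else 0; complementary pairs
# are exactly those summing to 5
base_codes <- function(bases) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 0L
  codes
}

revcomp_string <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Encode a DNA string as complex scores with prefix sums
#'
#' Each base maps to a unit complex score (A -> 1, T -> -1, C -> i, G -> -i),
#' so a window that is the reverse complement of another contributes the
#' exact negative of its score sum: complementary pairs cancel. Prefix sums
#' allow any window sum in O(1). Positions outside {A,C,G,T} (and, when
#' requested, soft-masked positions) are flagged invalid; a window containing
#' an invalid position is excluded from all candidacy.
#'
#' @param bases Uppercase DNA string.
#' @param masked Optional logical vector (same length as `bases`) of
#'   positions to treat as invalid.
#' @return A list of class `"encoded_seq"` with elements `n`, `scores`
#'   (complex, one per base), `prefix` (complex, length n+1, `prefix[1]` = 0),
#'   `valid` (logical) and `invalid_prefix` (cumulative invalid counts,
#'   length n+1).
#' @export
encode_sequence <- function(bases, masked = NULL) {
  codes <- base_codes(bases)
  n <- length(codes)
  valid <- codes != 0L
  if (!is.null(masked)) {
    stopifnot(length(masked) == n)
    valid <- valid & !masked
  }
  lut <- c(1 + 0i, 0 + 1i, 0 - 1i, -1 + 0i) # A, C, G, T
  scores <- complex(n)
  scores[valid] <- lut[codes[valid]]
  structure(list(
    n = n,
    codes = codes,
    scores = scores,
    prefix = c(0 + 0i, cumsum(scores)),
    valid = valid,
    invalid_prefix = c(0L, cumsum(!valid))
  ), class = "encoded_seq")
}

# complex window sums of width w for all start positions 1..n-w+1
window_sums <- function(enc, w) {
  if (enc$n < w) return(complex(0))
  enc$prefix[(w + 1L):(enc$n + 1L)] - enc$prefix[1:(enc$n - w + 1L)]
}

# TRUE where the w-window starting at each position contains no invalid base
window_valid <- function(enc, w) {
  if (enc$n < w) return(logical(0))
  enc$invalid_prefix[(w + 1L):(enc$n + 1L)] ==
    enc$invalid_prefix[1:(enc$n - w + 1L)]
}

#' Screen for potential TIR pairs by complex window sums
#'
#' Enumerates all window pairs (left, right) of width `cfg$tir_len` whose
#' implied element body span lies in `[cfg$min_len, cfg$max_len]` and whose
#' combined complex score C = sum(left window) + sum(right window) satisfies
#' |Re(C)| + |Im(C)| <= `cfg$score_tolerance`. Every complementary aligned
#' pair contributes zero to C, so a perfect TIR pair gives C = 0 and each
#' mismatched pair adds an L1 norm of exactly 2. The screen is a necessary
#' condition only (mismatches at symmetric positions can cancel);
#' [verify_tir()] must confirm every pair position-wise.
#'
#' @param enc An `"encoded_seq"` from [encode_sequence()].
#' @param cfg A [mite_config()].
#' @return A data.frame with columns `left_start`, `right_start` (1-based
#'   window starts), exhaustive over all qualifying pairs with both windows
#'   fully valid.
#' @export
screen_tir_pairs <- function(enc, cfg) {
  w <- cfg$tir_len
  W <- window_sums(enc, w)
  ok <- window_valid(enc, w)
  x <- Re(W); y <- Im(W)
  out_l <- list(); out_r <- list(); k <- 0L
  for (d in seq.int(cfg$min_len, cfg$max_len)) {
    m <- enc$n - d + 1L
    if (m < 1L) break
    il <- 1:m
    ir <- il + (d - w)
    l1 <- abs(x[il] + x[ir]) + abs(y[il] + y[ir])
    hit <- which(l1 <= cfg$score_tolerance & ok[il] & ok[ir])
    if (length(hit) > 0L) {
      k <- k + 1L
      out_l[[k]] <- hit
      out_r[[k]] <- hit + (d - w)
    }
  }
  data.frame(left_start = as.integer(unlist(out_l)),
             right_start = as.integer(unlist(out_r)))
}

#' Verify a TIR pair position-wise
#'
#' Aligns left-arm position k with right-arm position (tir_len - 1 - k) and
#' counts pairs that are not Watson-Crick complements. This is the exact
#' structural check behind the complex-sum screen: the screen is order
#' insensitive and can be fooled by compensating mismatches, the
#' position-wise count cannot.
#'
#' @param bases Uppercase DNA string.
#' @param left_start,right_start 1-based starts of the two arms.
#' @param tir_len Arm length.
#' @param max_mismatch Maximum tolerated non-complementary pairs.
#' @return A list with `accepted` (logical) and `mismatches` (count).
#' @export
verify_tir <- function(bases, left_start, right_start, tir_len,
                       max_mismatch = 1L) {
  codes <- base_codes(bases)
  stopifnot(left_start >= 1L, right_start + tir_len - 1L <= length(codes))
  k <- 0:(tir_len - 1L)
  l <- codes[left_start + k]
  r <- codes[right_start + (tir_len - 1L) - k]
  mism <- sum(l == 0L | r == 0L | l + r != 5L)
  list(accepted = mism <= max_mismatch, mismatches = as.integer(mism))
}

#' Find the target site duplication flanking a verified element body
#'
#' Searches lengths from `cfg$tsd_max` down to `cfg$tsd_min` for a direct
#' repeat immediately outside the body `[start, end]`: the `L` bases ending
#' at `start - 1` must equal, as exact strings of unambiguous bases, the
#' `L` bases starting at `end + 1`. The longest qualifying repeat wins. A
#' flank running off the contig simply disqualifies that length.
#'
#' @param bases Uppercase DNA string of the contig.
#' @param start,end 1-based inclusive bounds of the element body.
#' @param cfg A [mite_config()].
#' @return The TSD string, or `NA_character_` if no length qualifies.
#' @export
find_tsd <- function(bases, start, end, cfg) {
  n <- nchar(bases)
  for (L in seq.int(cfg$tsd_max, cfg$tsd_min)) {
    if (start - L < 1L || end + L > n) next
    left <- substr(bases, start - L, start - 1L)
    if (grepl("[^ACGT]", left)) next
    right <- substr(bases, end + 1L, end + L)
    if (left == right) return(left)
  }
  NA_character_
}

# Vectorized screen+verify for one encoded chunk. Returns a data.frame of
# verified TIR-pair spans (start, end 1-based inclusive, mismatches), with
# the whole body required to be free of invalid bases.
scan_encoded <- function(enc, cfg) {
  w <- cfg$tir_len
  n <- enc$n
  if (n < cfg$min_len) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  }
  W <- window_sums(enc, w)
  ok <- window_valid(enc, w)
  x <- Re(W); y <- Im(W)
  codes <- enc$codes
  ip <- enc$invalid_prefix
  starts <- list(); ends <- list(); mms <- list(); nk <- 0L
  for (d in seq.int(cfg$min_len, min(cfg$max_len, n))) {
    m <- n - d + 1L
    if (m < 1L) break
    il <- 1:m
    ir <- il + (d - w)
    l1 <- abs(x[il] + x[ir]) + abs(y[il] + y[ir])
    hit <- which(l1 <= cfg$score_tolerance &
                   (ip[il + d] - ip[il]) == 0L)
    if (length(hit) == 0L) next
    mm <- integer(length(hit))
    for (k in 0:(w - 1L)) {
      mm <- mm + (codes[hit + k] + codes[hit + d - 1L - k] != 5L)
    }
    keep <- mm <= cfg$max_tir_mismatch
    if (any(keep)) {
      nk <- nk + 1L
      starts[[nk]] <- hit[keep]
      ends[[nk]] <- hit[keep] + d - 1L
      mms[[nk]] <- mm[keep]
    }
  }
  data.frame(start = as.integer(unlist(starts)),
             end = as.integer(unlist(ends)),
             mismatches = as.integer(unlist(mms)))
}

#' Scan one chromosome for MITE candidates
#'
#' Composes the complex-sum screen, position-wise TIR verification, TSD
#' search and flank extraction. Long chromosomes are processed in chunks of
#' `cfg$chunk_size` with an overlap of `max_len + 2 * tsd_max` so no
#' candidate straddling a chunk boundary is lost; duplicate detections from
#' the overlap are removed and results are identical to an unchunked scan.
#'
#' @param bases Chromosome sequence: a character scalar, [Biostrings::DNAString]
#'   or single-element [Biostrings::DNAStringSet].
#' @param seq_id Sequence name recorded in the output.
#' @param cfg A [mite_config()].
#' @param mask Optional [IRanges::IRanges] of soft-masked regions; honored
#'   only when `cfg$skip_masked` is `TRUE`.
#' @return A data.frame of class `"mite_candidates"` with columns `seq_id`,
#'   `start`, `end` (1-based inclusive element body bounds), `tir_len`,
#'   `tir_mismatches`, `tsd`, `body`, `left_flank`, `right_flank`, sorted by
#'   (start, end).
#' @export
scan_chromosome <- function(bases, seq_id = "seq", cfg = mite_config(),
                            mask = NULL) {
  if (inherits(bases, "DNAStringSet")) {
    stopifnot(length(bases) == 1L)
    if (!is.null(names(bases))) seq_id <- names(bases)[1]
    bases <- as.character(bases[[1]])
  } else if (inherits(bases, "DNAString")) {
    bases <- as.character(bases)
  }
  n <- nchar(bases)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), tir_len = integer(0),
                      tir_mismatches = integer(0), tsd = character(0),
                      body = character(0), left_flank = character(0),
                      right_flank = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("mite_candidates", "data.frame")
  if (n < cfg$min_len) return(empty)

  masked <- NULL
  if (cfg$skip_masked && !is.null(mask) && length(mask) > 0L) {
    masked <- logical(n)
    hits <- IRanges::restrict(mask, start = 1L, end = n)
    for (j in seq_along(hits)) {
      masked[IRanges::start(hits)[j]:IRanges::end(hits)[j]] <- TRUE
    }
  }

  step <- cfg$chunk_size - cfg$chunk_overlap
  chunk_starts <- if (n <= cfg$chunk_size) 1L else
    seq.int(1L, n - cfg$chunk_overlap, by = step)
  pairs <- vector("list", length(chunk_starts))
  for (ci in seq_along(chunk_starts)) {
    cs <- chunk_starts[ci]
    ce <- min(n, cs + cfg$chunk_size - 1L)
    enc <- encode_sequence(substr(bases, cs, ce),
                           masked = if (is.null(masked)) NULL else masked[cs:ce])
    p <- scan_encoded(enc, cfg)
    if (nrow(p) > 0L) {
      p$start <- p$start + cs - 1L
      p$end <- p$end + cs - 1L
    }
    pairs[[ci]] <- p
  }
  pairs <- do.call(rbind, pairs)
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs[!duplicated(pairs[c("start", "end")]), , drop = FALSE]

  tsd <- vapply(seq_len(nrow(pairs)), function(i) {
    find_tsd(bases, pairs$start[i], pairs$end[i], cfg)
  }, character(1))
  keep <- !is.na(tsd)
  pairs <- pairs[keep, , drop = FALSE]
  tsd <- tsd[keep]
  if (nrow(pairs) == 0L) return(empty)

  ord <- order(pairs$start, pairs$end)
  pairs <- pairs[ord, , drop = FALSE]
  tsd <- tsd[ord]
  fl <- extract_flanks(bases, pairs$start, pairs$end, nchar(tsd),
                       flank_len = cfg$flank_len)
  out <- data.frame(
    seq_id = seq_id,
    start = pairs$start,
    end = pairs$end,
    tir_len = cfg$tir_len,
    tir_mismatches = pairs$mismatches,
    tsd = tsd,
    body = substring(bases, pairs$start, pairs$end),
    left_flank = fl$left,
    right_flank = fl$right,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("mite_candidates", "data.frame")
  out
}
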