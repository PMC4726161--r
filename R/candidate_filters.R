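#' Normalized Lempel-Ziv (LZ76) sequence complexity
#'
#' Parses the sequence by the exhaustive production history of Lempel and
#' Ziv (1976): scanning left to right, a phrase closes at the first
#' extension that cannot be copied (with self-overlap) from the preceding
#' sequence; the final, possibly reproducible, phrase also counts. The
#' phrase count c(n) is normalized as c(n) * log4(n) / n over the 4-letter
#' DNA alphabet, so uniform-random sequences approach 1 while repetitive,
#' low-complexity sequences fall well below. Element bodies scoring under
#' the configured threshold (default 0.675) are filtered as false positives.
#'
#' @param seq DNA string over {A,C,G,T}, length >= 2.
#' @return The normalized complexity value (non-negative real).
#' @examples
#' lz_complexity(strrep("A", 100))  # ~0.066, far below 0.675
#' @export
lz_complexity <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) {
    stop("lz_complexity is undefined for sequences shorter than 2 bases",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop("lz_complexity requires a sequence over {A,C,G,T}", call. = FALSE)
  }
  lz76_phrase_count(seq) * (log(n) / log(4)) / n
}

#' Detect homopolymer / dinucleotide stretches in a TIR arm
#'
#' Flags arms containing a run of length >= `min_stretch` that is periodic
#' with period 1 (e.g. `AAAAAAAA`) or period 2 (e.g. `ATATATAT`). A
#' position-2 autocorrelation run covers both cases: a window of length L
#' is period-1 or period-2 exactly when s[k] == s[k+2] holds for its first
#' L-2 positions.
#'
#' @param tir TIR arm string.
#' @param min_stretch Minimum disqualifying stretch length (nt).
#' @return `TRUE` if a stretch is present.
#' @export
has_long_stretch <- function(tir, min_stretch = 8L) {
  n <- nchar(tir)
  if (n < min_stretch) return(FALSE)
  ch <- strsplit(tir, "", fixed = TRUE)[[1]]
  same2 <- ch[1:(n - 2L)] == ch[3:n]
  r <- rle(same2)
  any(r$values & r$lengths >= min_stretch - 2L)
}

#' Check TIR base composition
#'
#' A TIR arm passes only if both its G+C fraction and its A+T fraction are
#' at least `min_frac` (default 20%); heavily skewed arms are filtered.
#'
#' @param tir TIR arm string over {A,C,G,T}.
#' @param min_frac Minimum fraction for each of G+C and A+T.
#' @return `TRUE` if composition is acceptable.
#' @export
tir_composition_ok <- function(tir, min_frac = 0.20) {
  ch <- strsplit(tir, "", fixed = TRUE)[[1]]
  gc <- mean(ch %in% c("G", "C"))
  at <- mean(ch %in% c("A", "T"))
  gc >= min_frac && at >= min_frac
}

#' The 'TA' rule for dinucleotide target sites
#'
#' Insertions that duplicate only two bases are credible MITE targets only
#' at TA sites (the Tourist/Stowaway signature); a 2-nt TSD other than
#' `"TA"` marks a false positive. Longer TSDs are unconstrained.
#'
#' @param tsd TSD string of length 2-10.
#' @return `TRUE` if the TSD is acceptable.
#' @export
tsd_ta_ok <- function(tsd) {
  nchar(tsd) != 2L || tsd == "TA"
}

#' Apply the four false-positive filters to scanned candidates
#'
#' A candidate passes only if: (1) neither TIR arm contains a homopolymer or
#' dinucleotide stretch of >= `cfg$min_stretch` nt, (2) both TIR arms have
#' G+C and A+T fractions >= `cfg$min_comp_frac`, (3) the LZ76 complexity of
#' the element body is >= `cfg$lz_threshold`, and (4) a 2-nt TSD is exactly
#' `"TA"`. All rules are evaluated for every candidate (no short-circuit) so
#' the report attributes every failure.
#'
#' @param candidates A `"mite_candidates"` data.frame from
#'   [scan_chromosome()].
#' @param cfg A [mite_config()].
#' @return A list with `passed` (the surviving candidates, original order)
#'   and `report` (one row per input candidate: `seq_id`, `start`, `end`,
#'   `verdict`, `failed_rules` comma-joined, `lz_value`).
#' @export
apply_filters <- function(candidates, cfg = mite_config()) {
  n <- nrow(candidates)
  if (n == 0L) {
    report <- data.frame(seq_id = character(0), start = integer(0),
                         end = integer(0), verdict = character(0),
                         failed_rules = character(0), lz_value = numeric(0),
                         stringsAsFactors = FALSE)
    return(list(passed = candidates, report = report))
  }
  w <- cfg$tir_len
  left_arm <- substr(candidates$body, 1L, w)
  right_arm <- substr(candidates$body, nchar(candidates$body) - w + 1L,
                      nchar(candidates$body))
  lz <- vapply(candidates$body, lz_complexity, numeric(1), USE.NAMES = FALSE)
  fail_lz <- lz < cfg$lz_threshold
  fail_stretch <- vapply(left_arm, has_long_stretch, logical(1),
                         min_stretch = cfg$min_stretch, USE.NAMES = FALSE) |
    vapply(right_arm, has_long_stretch, logical(1),
           min_stretch = cfg$min_stretch, USE.NAMES = FALSE)
  fail_comp <- !(vapply(left_arm, tir_composition_ok, logical(1),
                        min_frac = cfg$min_comp_frac, USE.NAMES = FALSE) &
                   vapply(right_arm, tir_composition_ok, logical(1),
                          min_frac = cfg$min_comp_frac, USE.NAMES = FALSE))
  fail_tsd <- !vapply(candidates$tsd, tsd_ta_ok, logical(1), USE.NAMES = FALSE)

  failed <- cbind(lz_complexity = fail_lz, tir_stretch = fail_stretch,
                  tir_composition = fail_comp, tsd_ta = fail_tsd)
  verdict <- ifelse(rowSums(failed) == 0L, "pass", "fail")
  failed_rules <- apply(failed, 1L, function(f) {
    paste(colnames(failed)[f], collapse = ",")
  })
  report <- data.frame(
    seq_id = candidates$seq_id,
    start = candidates$start,
    end = candidates$end,
    verdict = verdict,
    failed_rules = failed_rules,
    lz_value = lz,
    stringsAsFactors = FALSE
  )
  passed <- candidates[verdict == "pass", , drop = FALSE]
  rownames(passed) <- NULL
  class(passed) <- class(candidates)
  list(passed = passed, report = report)
}
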