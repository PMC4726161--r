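#' Extract the genomic flanks outside a candidate's TSDs
#'
#' The left flank is the up-to-`flank_len` bases immediately 5' of the left
#' TSD copy; the right flank the up-to-`flank_len` bases immediately 3' of
#' the right copy (layout flank-TSD-TIR...TIR-TSD-flank). Flanks are clipped
#' at contig ends and may be empty.
#'
#' @param bases Contig sequence string.
#' @param start,end 1-based inclusive element body bounds (vectorized).
#' @param tsd_len TSD length(s).
#' @param flank_len Maximum flank length (nt).
#' @return A list with character vectors `left` and `right`.
#' @export
extract_flanks <- function(bases, start, end, tsd_len, flank_len = 50L) {
  n <- nchar(bases)
  lf_end <- start - tsd_len - 1L
  lf_start <- pmax(1L, start - tsd_len - flank_len)
  rf_start <- end + tsd_len + 1L
  rf_end <- pmin(n, end + tsd_len + flank_len)
  left <- ifelse(lf_end >= lf_start, substring(bases, lf_start, lf_end), "")
  right <- ifelse(rf_end >= rf_start, substring(bases, rf_start, rf_end), "")
  list(left = as.character(left), right = as.character(right))
}

#' Count matched bases between two flanks
#'
#' Number of identical aligned columns in the optimal end-gap-free global
#' alignment of the two flanks (match +1, mismatch -1, gap -2 by default).
#' Two flanks sharing >= 25 of 50 bases are treated as the same insertion
#' context. Empty flanks never match.
#'
#' @param f1,f2 Flank strings (possibly empty).
#' @param scoring Alignment parameters.
#' @return Integer match count.
#' @export
flank_matches <- function(f1, f2,
                          scoring = list(match = 1, mismatch = -1,
                                         gap_opening = 0, gap_extension = 2)) {
  if (nchar(f1) == 0L || nchar(f2) == 0L) return(0L)
  as.integer(Biostrings::nmatch(overlap_alignment(f1, f2, scoring)))
}

#' Keep only family members with divergent flanks
#'
#' Within one family, members are processed in genomic order; a member is
#' dropped when its left flank matches a retained member's left flank at no
#' fewer than `threshold` bases, or its right flank matches a retained member's
#' right flank likewise. Left and right flanks are never cross-compared,
#' and comparisons run against the retained set only, so a dropped member
#' does not disqualify later members. Shared flanks mean the copies were
#' not placed by independent transposition (e.g. a segmental duplication),
#' so only the first such copy counts.
#'
#' @param members Data.frame of one family's members with `seq_id`, `start`,
#'   `end`, `left_flank`, `right_flank`.
#' @param threshold Minimum matched bases that marks two flanks as shared.
#' @param scoring Alignment parameters for [flank_matches()].
#' @return The retained subset, in genomic order.
#' @export
filter_family_members <- function(members, threshold = 25L,
                                  scoring = list(match = 1, mismatch = -1,
                                                 gap_opening = 0,
                                                 gap_extension = 2)) {
  if (nrow(members) == 0L) return(members)
  ord <- order(members$seq_id, members$start, members$end)
  members <- members[ord, , drop = FALSE]
  retained <- integer(0)
  for (i in seq_len(nrow(members))) {
    similar <- FALSE
    for (r in retained) {
      if (flank_matches(members$left_flank[i], members$left_flank[r],
                        scoring) >= threshold ||
          flank_matches(members$right_flank[i], members$right_flank[r],
                        scoring) >= threshold) {
        similar <- TRUE
        break
      }
    }
    if (!similar) retained <- c(retained, i)
  }
  out <- members[retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the representative member of a family
#'
#' Each member is scored by the sum of optimal local alignment scores of
#' its body against every other retained member's body; the member with
#' the highest total is the representative (ties broken by ascending
#' seq_id, then start). Unlike a multiple-alignment consensus, the
#' representative is a real genomic copy with exact coordinates.
#'
#' @param members One family's retained members (data.frame with `body`).
#' @param scoring Local alignment parameters (default match +2,
#'   mismatch -3, gap opening -5, gap extension -2).
#' @return The row index (within `members`) of the representative.
#' @export
select_representative <- function(members,
                                  scoring = list(match = 2, mismatch = -3,
                                                 gap_opening = 5,
                                                 gap_extension = 2)) {
  n <- nrow(members)
  if (n == 1L) return(1L)
  ord <- order(members$seq_id, members$start)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- local_alignment_score(members$body[i], members$body[j], scoring)
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  totals <- rowSums(S)
  # argmax with deterministic (seq_id, start) tie-break
  best <- ord[which.max(totals[ord])]
  as.integer(best)
}

#' Validate families by flank divergence and finalize the family set
#'
#' Applies [filter_family_members()] to every family, retains families with
#' at least `cfg$min_members` surviving members, and selects a
#' representative for each. The returned object records, per input family,
#' the member counts before and after flank filtration for auditing.
#'
#' @param clustered Output of [cluster_candidates()] /
#'   [drop_small_families()].
#' @param cfg A [mite_config()].
#' @return A list of class `"mite_families"` with `members` (validated
#'   members, columns of the input plus `member_id` and
#'   `is_representative`), `families` (one row per retained family:
#'   `family_id`, `n_members`, representative `seq_id`, `start`, `end`,
#'   `tir_len`, `tsd`, `body`), and `flank_audit` (per input family:
#'   members before/after, retained flag).
#' @export
finalize_families <- function(clustered, cfg = mite_config()) {
  fam_ids <- unique(clustered$family_id)
  members_list <- list()
  fam_rows <- list()
  audit <- list()
  kept <- 0L
  for (fid in fam_ids) {
    fam <- clustered[clustered$family_id == fid, , drop = FALSE]
    retained <- filter_family_members(fam, threshold = cfg$flank_match_threshold,
                                      scoring = cfg$flank_scoring)
    ok <- nrow(retained) >= cfg$min_members
    audit[[length(audit) + 1L]] <- data.frame(
      family_id = fid, members_before = nrow(fam),
      members_after = nrow(retained), retained = ok,
      stringsAsFactors = FALSE)
    if (!ok) next
    kept <- kept + 1L
    rep_i <- select_representative(retained, scoring = cfg$local_scoring)
    retained$member_id <- sprintf("%s.m%03d", fid, seq_len(nrow(retained)))
    retained$is_representative <- seq_len(nrow(retained)) == rep_i
    members_list[[kept]] <- retained
    fam_rows[[kept]] <- data.frame(
      family_id = fid,
      n_members = nrow(retained),
      seq_id = retained$seq_id[rep_i],
      start = retained$start[rep_i],
      end = retained$end[rep_i],
      tir_len = retained$tir_len[rep_i],
      tsd = retained$tsd[rep_i],
      body = retained$body[rep_i],
      stringsAsFactors = FALSE)
  }
  empty_members <- data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    tir_len = integer(0), tir_mismatches = integer(0), tsd = character(0),
    body = character(0), left_flank = character(0),
    right_flank = character(0), family_id = character(0),
    is_seed = logical(0), member_id = character(0),
    is_representative = logical(0), stringsAsFactors = FALSE)
  out <- list(
    members = if (kept > 0L) do.call(rbind, members_list) else empty_members,
    families = if (kept > 0L) do.call(rbind, fam_rows) else
      data.frame(family_id = character(0), n_members = integer(0),
                 seq_id = character(0), start = integer(0), end = integer(0),
                 tir_len = integer(0), tsd = character(0), body = character(0),
                 stringsAsFactors = FALSE),
    flank_audit = if (length(audit) > 0L) do.call(rbind, audit) else
      data.frame(family_id = character(0), members_before = integer(0),
                 members_after = integer(0), retained = logical(0),
                 stringsAsFactors = FALSE)
  )
  rownames(out$members) <- NULL
  class(out) <- "mite_families"
  out
}

#' @export
print.mite_families <- function(x, ...) {
  cat(sprintf("MITE families: %d families, %d validated members\n",
              nrow(x$families), nrow(x$members)))
  if (nrow(x$families) > 0L) {
    print(utils::head(x$families[c("family_id", "n_members", "seq_id",
                                   "start", "end", "tsd")], 10L))
  }
  invisible(x)
}
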