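# Shared pairwiseAlignment wrappers ------------------------------------------

sub_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

# end-gap-free global alignment (Biostrings type "overlap")
overlap_alignment <- function(a, b, scoring) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = sub_matrix(scoring),
    gapOpening = abs(scoring$gap_opening),
    gapExtension = abs(scoring$gap_extension),
    type = "overlap")
}

local_alignment_score <- function(a, b, scoring) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = sub_matrix(scoring),
    gapOpening = abs(scoring$gap_opening),
    gapExtension = abs(scoring$gap_extension),
    type = "local", scoreOnly = TRUE)
}

#' Identity and coverage statistics for a sequence pair
#'
#' Aligns the two sequences globally with free end gaps and reports the
#' clustering statistics: `identity` is the number of identical aligned
#' bases divided by the length of the shorter sequence, `coverage` the
#' aligned span (first to last aligned column, projected on the longer
#' sequence) divided by the length of the longer sequence.
#'
#' @param a,b Non-empty DNA strings.
#' @param scoring Alignment parameters; defaults to match +1, mismatch -1,
#'   gap -2 per base.
#' @return A list with `matches`, `aligned_span`, `identity`, `coverage`.
#' @export
pairwise_stats <- function(a, b,
                           scoring = list(match = 1, mismatch = -1,
                                          gap_opening = 0, gap_extension = 2)) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (nchar(a) <= nchar(b)) {
    shorter <- a; longer <- b
  } else {
    shorter <- b; longer <- a
  }
  aln <- overlap_alignment(shorter, longer, scoring)
  matches <- Biostrings::nmatch(aln)
  span <- IRanges::end(Biostrings::subject(aln)) -
    IRanges::start(Biostrings::subject(aln)) + 1L
  list(matches = as.integer(matches),
       aligned_span = as.integer(span),
       identity = matches / nchar(shorter),
       coverage = span / nchar(longer))
}

#' Cluster candidates into MITE families
#'
#' Greedy incremental clustering in the longest-first style: candidates are
#' sorted by (length descending, seq_id, start); the first unassigned
#' candidate seeds a new family, and each subsequent candidate joins the
#' first existing family whose seed it matches at identity >=
#' `cfg$cluster_identity` (matches / shorter length) and coverage >=
#' `cfg$cluster_coverage` (aligned span / longer length). Membership is
#' evaluated against the family seed only, so assignments are deterministic.
#'
#' @param candidates A `"mite_candidates"` data.frame (normally the
#'   filter-passing set).
#' @param cfg A [mite_config()].
#' @return The candidates with an added `family_id` column and a logical
#'   `is_seed` column, classed `"mite_clustered"`.
#' @export
cluster_candidates <- function(candidates, cfg = mite_config()) {
  n <- nrow(candidates)
  out <- candidates
  out$family_id <- character(n)
  out$is_seed <- logical(n)
  if (n == 0L) {
    class(out) <- c("mite_clustered", "data.frame")
    return(out)
  }
  ord <- order(-nchar(candidates$body), candidates$seq_id, candidates$start)
  seed_idx <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (s in seq_along(seed_idx)) {
      st <- pairwise_stats(out$body[i], out$body[seed_idx[s]],
                           scoring = cfg$cluster_scoring)
      if (st$identity >= cfg$cluster_identity &&
          st$coverage >= cfg$cluster_coverage) {
        out$family_id[i] <- out$family_id[seed_idx[s]]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      seed_idx <- c(seed_idx, i)
      out$family_id[i] <- sprintf("FAM%04d", length(seed_idx))
      out$is_seed[i] <- TRUE
    }
  }
  class(out) <- c("mite_clustered", "data.frame")
  out
}

#' Drop families with too few members
#'
#' Transposable elements show their mobility through copy number; clusters
#' with fewer than `min_members` members (default 3) are discarded as
#' likely false positives.
#'
#' @param clustered Output of [cluster_candidates()].
#' @param min_members Minimum family size retained.
#' @return The subset of rows belonging to retained families, same class.
#' @export
drop_small_families <- function(clustered, min_members = 3L) {
  if (nrow(clustered) == 0L) return(clustered)
  sizes <- table(clustered$family_id)
  keep <- names(sizes)[sizes >= min_members]
  out <- clustered[clustered$family_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(clustered)
  out
}

#' Cluster via the external cd-hit-est binary
#'
#' Writes the candidate bodies to FASTA, runs \command{cd-hit-est} with
#' thresholds mapped to the internal semantics (identity 0.80 computed
#' against the shorter sequence, alignment covering 0.99 of the longer),
#' and parses the `.clstr` file back into family assignments. Intended as a
#' cross-check of the internal greedy clusterer; when the binary is not on
#' the PATH the internal backend is used with a warning.
#'
#' @param candidates A `"mite_candidates"` data.frame.
#' @param cfg A [mite_config()].
#' @return Same shape as [cluster_candidates()].
#' @export
run_cdhit_backend <- function(candidates, cfg = mite_config()) {
  exe <- Sys.which("cd-hit-est")
  if (!nzchar(exe)) {
    warning("cd-hit-est not found on PATH; falling back to internal clustering")
    return(cluster_candidates(candidates, cfg))
  }
  if (nrow(candidates) == 0L) return(cluster_candidates(candidates, cfg))
  tmp <- tempfile("cdhit_")
  fa_in <- paste0(tmp, ".fa"); fa_out <- paste0(tmp, ".out")
  ids <- sprintf("cand%06d", seq_len(nrow(candidates)))
  writeLines(as.vector(rbind(paste0(">", ids), candidates$body)), fa_in)
  status <- system2(exe, c("-i", fa_in, "-o", fa_out,
                           "-c", format(cfg$cluster_identity),
                           "-aL", format(cfg$cluster_coverage),
                           "-s", "0", "-d", "0", "-G", "0", "-M", "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(paste0(fa_out, ".clstr"))) {
    stop("cd-hit-est failed (exit status ", status, ")", call. = FALSE)
  }
  assign <- parse_clstr(paste0(fa_out, ".clstr"))
  if (!setequal(names(assign), ids)) {
    stop("unparseable cd-hit-est cluster file: member ids do not round-trip",
         call. = FALSE)
  }
  out <- candidates
  out$family_id <- sprintf("FAM%04d", unname(assign[ids]))
  seeds <- !duplicated(out$family_id)
  out$is_seed <- seeds
  class(out) <- c("mite_clustered", "data.frame")
  out
}

# .clstr dialect: ">Cluster k" headers followed by member lines
# "0  201nt, >cand000001... *"
parse_clstr <- function(path) {
  lines <- readLines(path)
  cl <- cumsum(grepl("^>Cluster", lines))
  member <- !grepl("^>Cluster", lines)
  ids <- sub("^.*>([^.]+)\\.\\.\\..*$", "\\1", lines[member])
  stats::setNames(cl[member], ids)
}
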