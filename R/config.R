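#' Pipeline configuration
#'
#' Builds the full set of tunable thresholds used by the MITE detection
#' pipeline. Defaults are the standard operating point for plant genomes:
#' 10-nt TIRs with at most one non-complementary pair, element body between
#' 50 and 800 nt, TSDs of 2-10 nt, a Lempel-Ziv complexity cut of 0.675,
#' clustering at >=80% identity of the shorter and >=99% coverage of the
#' longer sequence, families kept at >=3 flank-validated members.
#'
#' @param tir_len TIR arm length scanned (nt).
#' @param min_len,max_len Bounds on the element body length (left TIR start
#'   through right TIR end, TSDs excluded), in nt.
#' @param tsd_min,tsd_max Bounds on the target-site-duplication length (nt);
#'   `tsd_max` may not exceed 10.
#' @param score_tolerance Upper bound on |Re(C)| + |Im(C)| for the complex
#'   window-sum screen; 2 corresponds to at most one mismatched TIR pair.
#' @param max_tir_mismatch Maximum non-complementary aligned pairs allowed
#'   by position-wise TIR verification.
#' @param lz_threshold Minimum normalized Lempel-Ziv (LZ76) complexity of
#'   the element body.
#' @param min_stretch Minimum length (nt) of a homopolymer or dinucleotide
#'   stretch inside a TIR arm that disqualifies a candidate.
#' @param min_comp_frac Minimum G+C and minimum A+T fraction required of
#'   each TIR arm.
#' @param cluster_identity Minimum identity (matches / shorter length) for
#'   family membership.
#' @param cluster_coverage Minimum coverage (aligned span / longer length)
#'   for family membership.
#' @param min_members Minimum validated members per retained family.
#' @param flank_len Length (nt) of genomic flank extracted outside each TSD.
#' @param flank_match_threshold Two flanks sharing at least this many
#'   aligned identical bases are considered the same insertion context.
#' @param chunk_size Chromosome scan chunk length (nt); results are
#'   chunk-invariant.
#' @param backend Clustering backend, `"internal"` (greedy longest-first)
#'   or `"cdhit"` (external \command{cd-hit-est}, falls back to internal).
#' @param skip_masked If `TRUE`, soft-masked (lowercase) genome positions
#'   are treated like ambiguous bases and excluded from candidacy.
#' @param cluster_scoring,flank_scoring Alignment parameters (lists with
#'   `match`, `mismatch`, `gap_opening`, `gap_extension`) for the
#'   end-gap-free global alignments used in clustering and flank
#'   comparison.
#' @param local_scoring Alignment parameters for the optimal local
#'   alignments behind representative selection.
#'
#' @return A validated list of class `"mite_config"`.
#' @examples
#' cfg <- mite_config()
#' cfg$lz_threshold
#' @export
mite_config <- function(tir_len = 10L,
                        min_len = 50L,
                        max_len = 800L,
                        tsd_min = 2L,
                        tsd_max = 10L,
                        score_tolerance = 2,
                        max_tir_mismatch = 1L,
                        lz_threshold = 0.675,
                        min_stretch = 8L,
                        min_comp_frac = 0.20,
                        cluster_identity = 0.80,
                        cluster_coverage = 0.99,
                        min_members = 3L,
                        flank_len = 50L,
                        flank_match_threshold = 25L,
                        chunk_size = 1000000L,
                        backend = c("internal", "cdhit"),
                        skip_masked = FALSE,
                        cluster_scoring = list(match = 1, mismatch = -1,
                                               gap_opening = 0, gap_extension = 2),
                        flank_scoring = list(match = 1, mismatch = -1,
                                             gap_opening = 0, gap_extension = 2),
                        local_scoring = list(match = 2, mismatch = -3,
                                             gap_opening = 5, gap_extension = 2)) {
  cfg <- list(
    tir_len = as.integer(tir_len),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    tsd_min = as.integer(tsd_min),
    tsd_max = as.integer(tsd_max),
    score_tolerance = as.numeric(score_tolerance),
    max_tir_mismatch = as.integer(max_tir_mismatch),
    lz_threshold = as.numeric(lz_threshold),
    min_stretch = as.integer(min_stretch),
    min_comp_frac = as.numeric(min_comp_frac),
    cluster_identity = as.numeric(cluster_identity),
    cluster_coverage = as.numeric(cluster_coverage),
    min_members = as.integer(min_members),
    flank_len = as.integer(flank_len),
    flank_match_threshold = as.integer(flank_match_threshold),
    chunk_size = as.integer(chunk_size),
    backend = match.arg(backend),
    skip_masked = isTRUE(skip_masked),
    cluster_scoring = cluster_scoring,
    flank_scoring = flank_scoring,
    local_scoring = local_scoring
  )
  # overlap needed so every element (body + both TSDs) fits inside one chunk
  cfg$chunk_overlap <- cfg$max_len + 2L * cfg$tsd_max
  class(cfg) <- "mite_config"
  validate_config(cfg)
}

#' @rdname mite_config
#' @param cfg A `"mite_config"` object.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
  }
  if (cfg$tir_len < 2L) fail("tir_len", "must be >= 2")
  if (cfg$min_len < 2L * cfg$tir_len) fail("min_len", "must be >= 2 * tir_len")
  if (cfg$max_len < cfg$min_len) fail("max_len", "must be >= min_len")
  if (cfg$tsd_min < 2L) fail("tsd_min", "must be >= 2")
  if (cfg$tsd_max > 10L) fail("tsd_max", "must be <= 10")
  if (cfg$tsd_max < cfg$tsd_min) fail("tsd_max", "must be >= tsd_min")
  if (cfg$score_tolerance < 0) fail("score_tolerance", "must be >= 0")
  if (cfg$max_tir_mismatch < 0L) fail("max_tir_mismatch", "must be >= 0")
  if (cfg$min_stretch < 2L) fail("min_stretch", "must be >= 2")
  if (cfg$min_comp_frac < 0 || cfg$min_comp_frac > 0.5)
    fail("min_comp_frac", "must be in [0, 0.5]")
  if (cfg$cluster_identity <= 0 || cfg$cluster_identity > 1)
    fail("cluster_identity", "must be in (0, 1]")
  if (cfg$cluster_coverage <= 0 || cfg$cluster_coverage > 1)
    fail("cluster_coverage", "must be in (0, 1]")
  if (cfg$min_members < 1L) fail("min_members", "must be >= 1")
  if (cfg$flank_len < 1L) fail("flank_len", "must be >= 1")
  if (cfg$flank_match_threshold < 1L) fail("flank_match_threshold", "must be >= 1")
  if (cfg$chunk_size < cfg$max_len + 2L * cfg$tsd_max + 1L)
    fail("chunk_size", "must exceed max_len + 2 * tsd_max")
  invisible(cfg)
}

#' Read pipeline settings from a plain-text configuration file
#'
#' The file uses simple `key: value` lines (a YAML mapping); keys are the
#' argument names of [mite_config()]. Values given in the file override the
#' defaults; anything supplied through `...` (e.g. command-line flags)
#' overrides the file.
#'
#' @param path Path to the configuration file, or `NULL` for defaults only.
#' @param ... Named overrides applied after the file.
#' @return A validated `"mite_config"`.
#' @export
parse_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("configuration file not found: ", path, call. = FALSE)
    }
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("configuration file is not a key: value mapping",
                             call. = FALSE)
    unknown <- setdiff(names(vals), names(formals(mite_config)))
    if (length(unknown) > 0) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(mite_config, vals)
}

#' @export
print.mite_config <- function(x, ...) {
  cat("MITE detection configuration\n")
  scalar <- vapply(x, function(v) is.atomic(v) && length(v) == 1L, logical(1))
  for (nm in names(x)[scalar]) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
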