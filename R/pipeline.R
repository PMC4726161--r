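#' Run the full MITE detection pipeline
#'
#' Scans every chromosome for TIR-pair/TSD candidates, applies the four
#' false-positive filters, pools candidates genome-wide, clusters them into
#' families, drops low-copy families, validates members by flank
#' divergence, and selects one representative per surviving family. When
#' `out_prefix` is given, writes `<prefix>.families.fa` (representatives),
#' `<prefix>.members.gff3` and `<prefix>.members.tsv` (all validated
#' members) and `<prefix>.log` (thresholds and per-stage counts). Outputs
#' contain no timestamps, so identical inputs reproduce byte-identical
#' files.
#'
#' @param genome A genome: path to a (gzipped) FASTA file or a named
#'   [Biostrings::DNAStringSet].
#' @param cfg A [mite_config()].
#' @param out_prefix Optional output path prefix.
#' @return A list of class `"mite_result"`: `families_object` (the
#'   `"mite_families"`), `candidates`, `filter_report`, `clustered`,
#'   `counts` (named integer vector over every stage), `config`, and
#'   `log` (the log lines).
#' @export
run_pipeline <- function(genome, cfg = mite_config(), out_prefix = NULL) {
  validate_config(cfg)
  if (is.character(genome)) genome <- read_genome(genome)
  if (!inherits(genome, "DNAStringSet")) {
    stop("genome must be a file path or a DNAStringSet", call. = FALSE)
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("genome sequences must carry unique names", call. = FALSE)
  }
  mask <- S4Vectors::metadata(genome)$mask

  cand_list <- lapply(seq_along(genome), function(i) {
    scan_chromosome(as.character(genome[[i]]), seq_id = names(genome)[i],
                    cfg = cfg,
                    mask = if (!is.null(mask)) mask[[names(genome)[i]]] else NULL)
  })
  candidates <- do.call(rbind, cand_list)
  class(candidates) <- c("mite_candidates", "data.frame")
  # canonical order, independent of per-chromosome execution order
  ord <- order(candidates$seq_id, candidates$start, candidates$end)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL

  filt <- apply_filters(candidates, cfg)
  clustered <- if (cfg$backend == "cdhit") {
    run_cdhit_backend(filt$passed, cfg)
  } else {
    cluster_candidates(filt$passed, cfg)
  }
  surviving <- drop_small_families(clustered, cfg$min_members)
  families <- finalize_families(surviving, cfg)

  counts <- c(
    sequences = length(genome),
    genome_bp = sum(Biostrings::width(genome)),
    candidates = nrow(candidates),
    filter_pass = nrow(filt$passed),
    families_clustered = length(unique(clustered$family_id)),
    families_min_members = length(unique(surviving$family_id)),
    members_min_members = nrow(surviving),
    families_final = nrow(families$families),
    members_final = nrow(families$members)
  )

  log_lines <- c(
    "# mitescan run log",
    "## configuration",
    vapply(names(cfg)[vapply(cfg, function(v) is.atomic(v) && length(v) == 1L,
                             logical(1))],
           function(nm) sprintf("%s: %s", nm, format(cfg[[nm]])), character(1)),
    "## stage counts",
    sprintf("%s: %d", names(counts), counts),
    "## dropped families (flank stage)",
    if (nrow(families$flank_audit) > 0L) {
      sprintf("%s: %d -> %d members (%s)",
              families$flank_audit$family_id,
              families$flank_audit$members_before,
              families$flank_audit$members_after,
              ifelse(families$flank_audit$retained, "retained", "dropped"))
    } else {
      "(none)"
    }
  )

  result <- structure(list(
    families_object = families,
    candidates = candidates,
    filter_report = filt$report,
    clustered = clustered,
    counts = counts,
    config = cfg,
    log = log_lines
  ), class = "mite_result")

  if (!is.null(out_prefix)) {
    write_family_fasta(families, paste0(out_prefix, ".families.fa"))
    write_member_table(families, paste0(out_prefix, ".members.gff3"), "gff3")
    write_member_table(families, paste0(out_prefix, ".members.tsv"), "tsv")
    writeLines(log_lines, paste0(out_prefix, ".log"))
  }
  result
}

#' @export
print.mite_result <- function(x, ...) {
  cat("MITE detection result\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
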