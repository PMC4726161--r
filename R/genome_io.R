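#' Read a genome from a (possibly gzipped) multi-FASTA file
#'
#' Each record becomes one chromosome/contig sequence. Sequence bodies are
#' uppercased; the soft-mask (lowercase runs in the input) is preserved as
#' per-sequence [IRanges::IRanges] in `metadata(x)$mask` so that masked
#' regions can optionally be excluded from scanning.
#'
#' @param path Path to a FASTA file, plain or gzip-compressed.
#' @return A [Biostrings::DNAStringSet], names taken from the FASTA header
#'   up to the first whitespace, with `metadata(x)$mask` holding the
#'   soft-masked ranges per sequence.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(raw) == 0L) {
    stop("no FASTA records found in: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in genome: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(raw) <- ids
  mask <- lapply(seq_along(raw), function(i) {
    lowercase_ranges(as.character(raw[[i]]))
  })
  names(mask) <- ids
  genome <- Biostrings::DNAStringSet(toupper(as.character(raw)))
  names(genome) <- ids
  S4Vectors::metadata(genome)$mask <- mask
  genome
}

# IRanges of lowercase (soft-masked) runs within one sequence string
lowercase_ranges <- function(s) {
  codes <- utf8ToInt(s)
  low <- codes >= 97L & codes <= 122L
  if (!any(low)) return(IRanges::IRanges())
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' Write one FASTA record per family (the representative copy)
#'
#' The record sequence is the representative member's element body (left TIR
#' start through right TIR end, TSDs excluded). The header carries the family
#' id, the representative's genomic location (1-based inclusive), TIR length,
#' TSD sequence and the validated member count.
#'
#' @param families A `"mite_families"` object from [finalize_families()] or
#'   the `families` component of a pipeline result.
#' @param path Output file path.
#' @export
write_family_fasta <- function(families, path) {
  families <- as_mite_families(families)
  fam <- families$families
  if (nrow(fam) == 0L) {
    warning("no families to write; creating empty file: ", path)
    ok <- file.create(path)
    if (!ok) stop("cannot write to: ", path, call. = FALSE)
    return(invisible(path))
  }
  headers <- sprintf(">%s %s:%d-%d TIR_len=%d TSD=%s members=%d",
                     fam$family_id, fam$seq_id, fam$start, fam$end,
                     fam$tir_len, fam$tsd, fam$n_members)
  lines <- as.vector(rbind(headers, fam$body))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to: ", path, call. = FALSE)
  invisible(path)
}

#' Write all validated family members as GFF3 or TSV
#'
#' Coordinates are emitted 1-based inclusive. GFF3 rows use feature type
#' `MITE` with attributes `ID`, `Parent` (the family), `TIR_len`,
#' `TIR_mismatches`, `TSD_seq` and `TSD_len`; the TSV holds the same
#' columns flat. Rows are ordered by (seq_id, start, end) so output is
#' deterministic.
#'
#' @param families A `"mite_families"` object.
#' @param path Output file path.
#' @param format `"gff3"` or `"tsv"`.
#' @export
write_member_table <- function(families, path, format = c("gff3", "tsv")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("gff3", "tsv")) {
    stop("unknown member table format: '", format, "' (use \"gff3\" or \"tsv\")",
         call. = FALSE)
  }
  format <- match.arg(format)
  families <- as_mite_families(families)
  mem <- families$members
  ord <- order(mem$seq_id, mem$start, mem$end)
  mem <- mem[ord, , drop = FALSE]
  if (format == "gff3") {
    lines <- "##gff-version 3"
    if (nrow(mem) > 0L) {
      attrs <- sprintf(
        "ID=%s;Parent=%s;TIR_len=%d;TIR_mismatches=%d;TSD_seq=%s;TSD_len=%d",
        gff3_escape(mem$member_id), gff3_escape(mem$family_id),
        mem$tir_len, mem$tir_mismatches,
        gff3_escape(mem$tsd), nchar(mem$tsd))
      rows <- sprintf("%s\tmitescan\tMITE\t%d\t%d\t.\t+\t.\t%s",
                      mem$seq_id, mem$start, mem$end, attrs)
      lines <- c(lines, rows)
    }
    writeLines(lines, path)
  } else {
    tab <- data.frame(
      member_id = mem$member_id,
      family_id = mem$family_id,
      seq_id = mem$seq_id,
      start = mem$start,
      end = mem$end,
      tir_len = mem$tir_len,
      tir_mismatches = mem$tir_mismatches,
      tsd_seq = mem$tsd,
      tsd_len = nchar(mem$tsd),
      is_representative = mem$is_representative,
      stringsAsFactors = FALSE
    )
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# percent-escape the characters reserved in GFF3 column 9
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

# accept either a mite_families object or a full pipeline result
as_mite_families <- function(x) {
  if (inherits(x, "mite_result")) x <- x$families_object
  if (!inherits(x, "mite_families")) {
    stop("expected a 'mite_families' object or pipeline result", call. = FALSE)
  }
  x
}
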