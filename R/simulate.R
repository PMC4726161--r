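#' Random DNA string
#'
#' Uniform over {A,C,G,T}, drawn from the current RNG state.
#'
#' @param n Length in bases.
#' @return A character scalar.
#' @export
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# draw one TIR arm that passes the composition and stretch filters
draw_tir_arm <- function(tir_len, cfg) {
  repeat {
    arm <- random_dna(tir_len)
    if (tir_composition_ok(arm, cfg$min_comp_frac) &&
        !has_long_stretch(arm, cfg$min_stretch)) {
      return(arm)
    }
  }
}

# substitute `m` positions of an arm with non-complement-preserving bases
mutate_arm <- function(arm, m) {
  if (m == 0L) return(arm)
  ch <- strsplit(arm, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), m)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Construct one synthetic MITE element
#'
#' Builds a structurally valid element: a random left TIR arm that passes
#' the composition and stretch filters, a right arm that is its reverse
#' complement with exactly `tir_mismatches` substitutions, an internal
#' spacer, and TSD copies appended outside the body. With
#' `body_mode = "random"` the spacer is uniform-random and the body is
#' resampled until its LZ76 complexity clears the configured threshold;
#' with `body_mode = "low_complexity"` the spacer is a short-motif repeat
#' and the body is required to fall below the threshold (a designed
#' negative for the complexity filter).
#'
#' @param body_len Element body length (left TIR start through right TIR
#'   end), within `[cfg$min_len, cfg$max_len]`.
#' @param tsd TSD string (length 2-10; a 2-nt TSD should be `"TA"` if the
#'   element is meant to survive filtration).
#' @param tir_mismatches Non-complementary pairs planted in the TIR.
#' @param cfg A [mite_config()].
#' @param body_mode `"random"` or `"low_complexity"`.
#' @return A list with `element` (TSD + body + TSD), `body`, `tir_left`,
#'   `tir_right`, `tsd`, `tir_mismatches`.
#' @export
make_mite <- function(body_len, tsd = "TA", tir_mismatches = 0L,
                      cfg = mite_config(), body_mode = "random") {
  tir_len <- cfg$tir_len
  if (body_len < 2L * tir_len) {
    stop("body_len must be at least 2 * tir_len", call. = FALSE)
  }
  if (body_len < cfg$min_len || body_len > cfg$max_len) {
    stop("body_len outside [min_len, max_len]", call. = FALSE)
  }
  if (nchar(tsd) < 2L || nchar(tsd) > 10L || grepl("[^ACGT]", tsd)) {
    stop("tsd must be 2-10 bases over {A,C,G,T}", call. = FALSE)
  }
  spacer_len <- body_len - 2L * tir_len
  for (try in 1:200) {
    left <- draw_tir_arm(tir_len, cfg)
    right <- mutate_arm(revcomp_string(left), tir_mismatches)
    if (!tir_composition_ok(right, cfg$min_comp_frac) ||
        has_long_stretch(right, cfg$min_stretch)) next
    spacer <- if (body_mode == "low_complexity") {
      motif <- random_dna(3L)
      substr(strrep(motif, ceiling(spacer_len / 3L)), 1L, spacer_len)
    } else {
      random_dna(spacer_len)
    }
    body <- paste0(left, spacer, right)
    lz <- lz_complexity(body)
    ok <- if (body_mode == "low_complexity") lz < cfg$lz_threshold
          else lz >= cfg$lz_threshold
    if (!ok) next
    return(list(element = paste0(tsd, body, tsd), body = body,
                tir_left = left, tir_right = right, tsd = tsd,
                tir_mismatches = as.integer(tir_mismatches)))
  }
  stop("could not construct an element satisfying the constraints", call. = FALSE)
}

# mutate spacer positions of a family's base body at the given rate,
# preserving the TIR arms; for random bodies the mutated copy must still
# clear the complexity threshold
mutate_body <- function(body, rate, cfg, body_mode = "random") {
  n <- nchar(body)
  w <- cfg$tir_len
  spacer_pos <- seq.int(w + 1L, n - w)
  for (try in 1:100) {
    ch <- strsplit(body, "", fixed = TRUE)[[1]]
    m <- stats::rbinom(1L, length(spacer_pos), rate)
    if (m > 0L) {
      pos <- sample(spacer_pos, m)
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
    }
    out <- paste(ch, collapse = "")
    if (body_mode == "low_complexity" ||
        lz_complexity(out) >= cfg$lz_threshold) {
      return(out)
    }
  }
  body
}

default_families_spec <- function(n_families, copies_per_family,
                                  substitution_rate, tsd, tir_mismatches,
                                  body_len_range) {
  data.frame(
    family_id = sprintf("plant%02d", seq_len(n_families)),
    copies = copies_per_family,
    body_len = sample(seq.int(body_len_range[1], body_len_range[2]),
                      n_families, replace = TRUE),
    tsd = tsd,
    tir_mismatches = as.integer(tir_mismatches),
    substitution_rate = substitution_rate,
    flank_mode = "divergent",
    body_mode = "random",
    stringsAsFactors = FALSE
  )
}

#' Generate a genome with planted MITE families and a truth table
#'
#' Plants synthetic MITE families into a uniform-random background at
#' non-overlapping loci separated by at least two flank lengths. Within a
#' family, copies share the body up to independent spacer substitutions at
#' `substitution_rate` (default 2%, keeping within-family identity well
#' above the 80% clustering threshold at full coverage). After assembly
#' every planted locus is verified: the longest detectable TSD equals the
#' planted TSD and, for `flank_mode = "divergent"` families, all pairwise
#' flank alignments stay below the flank-match threshold; offending
#' background regions are redrawn until the truth table is self-consistent.
#'
#' Designed negatives are available through `families_spec`: 2-copy
#' families (fail the minimum-member rule), `flank_mode = "identical"`
#' (collapse under flank validation), `body_mode = "low_complexity"`
#' (fail the LZ76 filter), non-`"TA"` 2-nt TSDs (fail the TA rule), and
#' `tir_mismatches = 2` (never verified as candidates).
#'
#' @param n_families,copies_per_family Family count and copies per family
#'   (used when `families_spec` is `NULL`).
#' @param genome_len Total background length (split evenly across
#'   `chromosomes`).
#' @param cfg A [mite_config()].
#' @param chromosomes Number of chromosomes; copies are distributed
#'   round-robin so families may span chromosomes.
#' @param substitution_rate Per-base spacer substitution rate within a
#'   family.
#' @param tsd TSD planted for every family (default families).
#' @param tir_mismatches TIR mismatches planted (default families).
#' @param body_len_range Range the per-family body length is drawn from.
#' @param families_spec Optional data.frame overriding the per-family
#'   design; columns `family_id`, `copies`, `body_len`, `tsd`,
#'   `tir_mismatches`, `substitution_rate`, `flank_mode`, `body_mode`.
#' @param max_rounds Bound on post-assembly repair rounds.
#' @return A list with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame: `family_id`, `copy`, `seq_id`, `start`, `end`
#'   1-based inclusive body bounds, `tsd`, `tir_mismatches`,
#'   `substitution_rate`, `flank_mode`, `body_mode`).
#' @export
generate_planted_genome <- function(n_families = 10L, copies_per_family = 5L,
                                    genome_len = 200000L, cfg = mite_config(),
                                    chromosomes = 1L,
                                    substitution_rate = 0.02,
                                    tsd = "TA", tir_mismatches = 0L,
                                    body_len_range = c(100L, 400L),
                                    families_spec = NULL,
                                    max_rounds = 30L) {
  spec <- if (is.null(families_spec)) {
    default_families_spec(n_families, copies_per_family, substitution_rate,
                          tsd, tir_mismatches, body_len_range)
  } else {
    families_spec
  }
  needed <- c("family_id", "copies", "body_len", "tsd", "tir_mismatches",
              "substitution_rate", "flank_mode", "body_mode")
  missing_cols <- setdiff(needed, names(spec))
  if (length(missing_cols) > 0L) {
    stop("families_spec lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  # per-family base elements and (for identical-flank families) shared flanks
  fam_state <- lapply(seq_len(nrow(spec)), function(f) {
    base <- make_mite(spec$body_len[f], tsd = spec$tsd[f],
                      tir_mismatches = spec$tir_mismatches[f], cfg = cfg,
                      body_mode = spec$body_mode[f])
    flanks <- if (spec$flank_mode[f] == "identical") {
      list(left = random_dna(cfg$flank_len), right = random_dna(cfg$flank_len))
    } else NULL
    list(base = base, flanks = flanks)
  })

  # unit = one planted copy; assigned round-robin to chromosomes
  units <- list()
  for (f in seq_len(nrow(spec))) {
    for (k in seq_len(spec$copies[f])) {
      body <- mutate_body(fam_state[[f]]$base$body, spec$substitution_rate[f],
                          cfg, body_mode = spec$body_mode[f])
      units[[length(units) + 1L]] <- list(fam = f, copy = k, body = body)
    }
  }
  chrom_of <- rep(seq_len(chromosomes), length.out = length(units))
  chrom_ids <- sprintf("chr%d", seq_len(chromosomes))
  chrom_len <- as.integer(genome_len %/% chromosomes)
  min_sep <- 2L * cfg$flank_len + 20L

  unit_seq <- function(u) {
    f <- u$fam
    el <- paste0(spec$tsd[f], u$body, spec$tsd[f])
    if (!is.null(fam_state[[f]]$flanks)) {
      paste0(fam_state[[f]]$flanks$left, el, fam_state[[f]]$flanks$right)
    } else {
      el
    }
  }
  body_offset <- function(u) {  # bases preceding the body within the unit
    f <- u$fam
    nchar(spec$tsd[f]) +
      if (is.null(fam_state[[f]]$flanks)) 0L else cfg$flank_len
  }

  # per-chromosome: shuffled unit order and background gap strings
  chrom_units <- lapply(seq_len(chromosomes), function(ci) {
    idx <- which(chrom_of == ci)
    if (length(idx) > 1L) idx[sample.int(length(idx))] else idx
  })
  gaps <- vector("list", chromosomes)
  for (ci in seq_len(chromosomes)) {
    k <- length(chrom_units[[ci]])
    widths <- vapply(units[chrom_units[[ci]]],
                     function(u) nchar(unit_seq(u)), integer(1))
    free <- chrom_len - sum(widths) - (k + 1L) * min_sep
    if (free < 0L) {
      stop("genome_len too small for the requested plantings; ",
           "increase genome_len", call. = FALSE)
    }
    extra <- if (k >= 0L && free > 0L) {
      tabulate(sample.int(k + 1L, free, replace = TRUE), nbins = k + 1L)
    } else {
      integer(k + 1L)
    }
    gaps[[ci]] <- vapply(min_sep + extra, random_dna, character(1))
  }

  assemble <- function() {
    seqs <- character(chromosomes)
    truth_rows <- list()
    for (ci in seq_len(chromosomes)) {
      pieces <- character(0)
      pos <- 0L
      g <- gaps[[ci]]
      for (j in seq_along(chrom_units[[ci]])) {
        ui <- chrom_units[[ci]][j]
        u <- units[[ui]]
        pieces <- c(pieces, g[j])
        pos <- pos + nchar(g[j])
        us <- unit_seq(u)
        start <- pos + body_offset(u) + 1L
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          unit = ui,
          family_id = spec$family_id[u$fam],
          copy = u$copy,
          seq_id = chrom_ids[ci],
          start = start,
          end = start + nchar(u$body) - 1L,
          tsd = spec$tsd[u$fam],
          tir_mismatches = spec$tir_mismatches[u$fam],
          substitution_rate = spec$substitution_rate[u$fam],
          flank_mode = spec$flank_mode[u$fam],
          body_mode = spec$body_mode[u$fam],
          stringsAsFactors = FALSE)
        pieces <- c(pieces, us)
        pos <- pos + nchar(us)
      }
      pieces <- c(pieces, g[length(g)])
      seqs[ci] <- paste(pieces, collapse = "")
    }
    list(seqs = seqs, truth = do.call(rbind, truth_rows))
  }

  # repair loop: redraw background (or shared flanks) until every planted
  # locus reports exactly its planted TSD and divergent-flank families
  # really have divergent flanks
  gap_index_of_unit <- function(ui) {
    ci <- chrom_of[ui]
    j <- match(ui, chrom_units[[ci]])
    list(ci = ci, left = j, right = j + 1L)
  }
  redraw_unit_gaps <- function(ui) {
    gi <- gap_index_of_unit(ui)
    gaps[[gi$ci]][gi$left] <<- random_dna(nchar(gaps[[gi$ci]][gi$left]))
    gaps[[gi$ci]][gi$right] <<- random_dna(nchar(gaps[[gi$ci]][gi$right]))
  }
  # point-mutate one background base at absolute position p next to unit ui
  # (bounds of the unit supplied); returns FALSE if p is not inside one of
  # the unit's two adjacent gaps
  mutate_gap_base <- function(ui, unit_lo, unit_hi, p) {
    gi <- gap_index_of_unit(ui)
    if (p < unit_lo) {
      g <- gaps[[gi$ci]][gi$left]
      loc <- nchar(g) - (unit_lo - 1L - p)
      side <- gi$left
    } else {
      g <- gaps[[gi$ci]][gi$right]
      loc <- p - unit_hi
      side <- gi$right
    }
    if (loc < 1L || loc > nchar(g)) return(FALSE)
    old <- substr(g, loc, loc)
    substr(g, loc, loc) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    gaps[[gi$ci]][side] <<- g
    TRUE
  }
  redraw_family_body <- function(f) {
    fam_state[[f]]$base <<- make_mite(spec$body_len[f], tsd = spec$tsd[f],
                                      tir_mismatches = spec$tir_mismatches[f],
                                      cfg = cfg,
                                      body_mode = spec$body_mode[f])
    for (ui in seq_along(units)) {
      if (units[[ui]]$fam == f) {
        units[[ui]]$body <<- mutate_body(fam_state[[f]]$base$body,
                                         spec$substitution_rate[f], cfg,
                                         body_mode = spec$body_mode[f])
      }
    }
  }
  # a planted copy is expected to survive scanning + filtration only if its
  # TIR verifies and no filter rule is designed to remove it
  expect_detected <- vapply(seq_len(nrow(spec)), function(f) {
    spec$tir_mismatches[f] <= cfg$max_tir_mismatch &&
      spec$body_mode[f] != "low_complexity" &&
      tsd_ta_ok(spec$tsd[f])
  }, logical(1))

  asm <- NULL
  for (round in seq_len(max_rounds)) {
    asm <- assemble()
    tr <- asm$truth
    dirty <- FALSE
    for (r in seq_len(nrow(tr))) {
      f <- units[[tr$unit[r]]]$fam
      chrom_str <- asm$seqs[match(tr$seq_id[r], chrom_ids)]
      # the planted TSD must be exactly what the scanner will report
      found <- find_tsd(chrom_str, tr$start[r], tr$end[r], cfg)
      bad_tsd <- spec$tir_mismatches[f] <= cfg$max_tir_mismatch &&
        (is.na(found) || found != tr$tsd[r])
      # the locus must yield exactly the planted candidate after filtration:
      # chance TSDs can promote shifted or nested TIR geometries into
      # competing candidates that would corrupt family membership
      ws <- max(1L, tr$start[r] - 60L)
      we <- min(nchar(chrom_str), tr$end[r] + 60L)
      loc <- scan_chromosome(substr(chrom_str, ws, we), "w", cfg)
      pass <- apply_filters(loc, cfg)$passed
      if (nrow(pass) > 0L) {          # window -> absolute coordinates
        pass$start <- pass$start + ws - 1L
        pass$end <- pass$end + ws - 1L
      }
      got <- paste(pass$start, pass$end, pass$tsd)
      want <- if (expect_detected[f]) {
        paste(tr$start[r], tr$end[r], tr$tsd[r])
      } else {
        character(0)
      }
      if (bad_tsd || !identical(sort(got), sort(want))) {
        extra <- pass[!(got %in% want), , drop = FALSE]
        # element core that is identical across the family's copies;
        # decoys whose direct repeat lies wholly inside it can only be
        # removed by redrawing the family body
        core_lo <- tr$start[r] - nchar(tr$tsd[r])
        core_hi <- tr$end[r] + nchar(tr$tsd[r])
        has_flanks <- !is.null(fam_state[[f]]$flanks)
        prot_lo <- if (has_flanks) core_lo - cfg$flank_len else core_lo
        prot_hi <- if (has_flanks) core_hi + cfg$flank_len else core_hi
        u <- units[[tr$unit[r]]]
        unit_lo <- tr$start[r] - body_offset(u)   # first base of the unit
        unit_hi <- unit_lo + nchar(unit_seq(u)) - 1L
        handled <- FALSE
        if (nrow(extra) > 0L) {
          for (x in seq_len(nrow(extra))) {
            L <- nchar(extra$tsd[x])
            win <- c(seq.int(extra$start[x] - L, extra$start[x] - 1L),
                     seq.int(extra$end[x] + 1L, extra$end[x] + L))
            bg <- win[win < prot_lo | win > prot_hi]
            if (extra$start[x] - L >= core_lo && extra$end[x] + L <= core_hi) {
              redraw_family_body(f)   # fully shared decoy
              handled <- TRUE
              break
            }
            if (length(bg) > 0L) {
              # break the chance direct repeat with one background mutation
              if (mutate_gap_base(tr$unit[r], unit_lo, unit_hi,
                                  bg[sample.int(length(bg), 1L)])) {
                handled <- TRUE
              }
            } else if (has_flanks) {
              fam_state[[f]]$flanks <- list(left = random_dna(cfg$flank_len),
                                            right = random_dna(cfg$flank_len))
              handled <- TRUE
            }
          }
        }
        if (!handled) redraw_unit_gaps(tr$unit[r])
        dirty <- TRUE
      }
    }
    # batch-fix every divergence violation in one round; redraws are
    # re-checked next round
    for (f in which(spec$flank_mode == "divergent" & spec$copies >= 2L)) {
      rows <- which(tr$family_id == spec$family_id[f])
      fl <- lapply(rows, function(r) {
        s <- asm$seqs[match(tr$seq_id[r], chrom_ids)]
        extract_flanks(s, tr$start[r], tr$end[r], nchar(tr$tsd[r]),
                       flank_len = cfg$flank_len)
      })
      for (a in seq_along(rows)) {
        for (b in seq_len(a - 1L)) {
          if (flank_matches(fl[[a]]$left, fl[[b]]$left,
                            cfg$flank_scoring) >= cfg$flank_match_threshold ||
              flank_matches(fl[[a]]$right, fl[[b]]$right,
                            cfg$flank_scoring) >= cfg$flank_match_threshold) {
            redraw_unit_gaps(tr$unit[rows[a]])
            dirty <- TRUE
            break
          }
        }
      }
    }
    if (!dirty) break
    if (round == max_rounds) {
      stop("could not reconcile planted loci with the background after ",
           max_rounds, " repair rounds", call. = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(asm$seqs)
  names(genome) <- chrom_ids
  truth <- asm$truth[order(asm$truth$family_id, asm$truth$copy), ]
  truth$unit <- NULL
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Write a planted-genome fixture to disk
#'
#' Writes `<prefix>.fa` (the genome) and `<prefix>.truth.tsv` (the truth
#' table, with the generating seed recorded in a header comment).
#'
#' @param sim Output of [generate_planted_genome()].
#' @param prefix Output path prefix.
#' @param seed Seed recorded in the truth-table header (informational).
#' @return The two paths, invisibly.
#' @export
write_simulation <- function(sim, prefix, seed = NA) {
  fa <- paste0(prefix, ".fa")
  tsv <- paste0(prefix, ".truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fa)
  con <- file(tsv, "w")
  on.exit(close(con))
  writeLines(sprintf("# mitescan simulation; seed=%s", format(seed)), con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, tsv))
}
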