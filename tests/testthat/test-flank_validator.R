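test_that("flank extraction follows the flank-TSD-body-TSD-flank layout", {
  set.seed(51)
  g <- random_seq(1000)
  # body at 1-based [101, 300] with a 2-nt TSD
  fl <- extract_flanks(g, 101L, 300L, 2L, flank_len = 50L)
  expect_identical(fl$left, substr(g, 49, 98))
  expect_identical(fl$right, substr(g, 303, 352))

  # near the contig start the left flank is clipped
  fl2 <- extract_flanks(g, 31L, 230L, 2L, flank_len = 50L)
  expect_identical(fl2$left, substr(g, 1, 28))
  expect_identical(nchar(fl2$left), 28L)

  # at the contig end the right flank can be empty
  fl3 <- extract_flanks(g, 801L, 998L, 2L, flank_len = 50L)
  expect_identical(fl3$right, "")
})

test_that("flank match counts come from the optimal pairwise alignment", {
  set.seed(52)
  f <- random_seq(50)
  expect_identical(flank_matches(f, f), 50L)
  expect_identical(flank_matches("", f), 0L)
  expect_identical(flank_matches(f, ""), 0L)
  # substitution load decreases the match count: a lightly substituted pair
  # stays near-identical, a heavily substituted one scores clearly lower
  # (though gapped realignment of chance matches keeps it above the naive
  # untouched-position count)
  substitute_at <- function(s, k) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in sample(50, k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  for (rep in 1:10) {
    m5 <- flank_matches(f, substitute_at(f, 5))
    m30 <- flank_matches(f, substitute_at(f, 30))
    expect_gte(m5, 40L)
    expect_lt(m30, m5)
  }
})

fam_with_flanks <- function(left, right, seq_id = "chr1") {
  n <- length(left)
  starts <- seq(1000L, by = 1000L, length.out = n)
  data.frame(seq_id = seq_id, start = starts, end = starts + 199L,
             tir_len = 10L, tir_mismatches = 0L, tsd = "TA",
             body = replicate(n, random_seq(200)),
             left_flank = left, right_flank = right,
             stringsAsFactors = FALSE)
}

test_that("members sharing a left or right flank collapse to the first copy", {
  set.seed(53)
  # the worked five-member case: left flanks of copies 1,2 near-identical,
  # right flanks of copies 4,5 near-identical -> copies 2 and 5 drop
  lf <- draw_divergent_flanks(4)
  rf <- draw_divergent_flanks(4)
  left <- c(lf[1], lf[1], lf[2], lf[3], lf[4])
  right <- c(rf[1], rf[2], rf[3], rf[4], rf[4])
  fam <- fam_with_flanks(left, right)
  kept <- filter_family_members(fam, threshold = 25L)
  expect_identical(kept$start, c(1000L, 3000L, 4000L))

  # mutually divergent flanks: everybody stays
  fam2 <- fam_with_flanks(draw_divergent_flanks(5), draw_divergent_flanks(5))
  expect_identical(nrow(filter_family_members(fam2, 25L)), 5L)

  # three identical left flanks: only one survivor
  same <- random_seq(50)
  fam3 <- fam_with_flanks(rep(same, 3), draw_divergent_flanks(3))
  expect_identical(nrow(filter_family_members(fam3, 25L)), 1L)
})

test_that("a dropped member does not disqualify later members", {
  set.seed(54)
  fl <- draw_divergent_flanks(2)
  a <- fl[1]
  b <- fl[2]
  # copy2 shares a left flank with copy1 (dropped); copy3 shares a left
  # flank with copy2 only -- it must survive because comparisons run
  # against the retained set
  fam <- fam_with_flanks(c(a, paste0(substr(a, 1, 30), substr(b, 31, 50)), b),
                         draw_divergent_flanks(3))
  # drop copy2 via its 30 shared bases with copy1; copy3 shares only
  # 20 bases with copy1
  kept <- filter_family_members(fam, threshold = 25L)
  expect_identical(kept$start, c(1000L, 3000L))
})

test_that("random 50-mer flank pairs rarely reach the 25-match bar", {
  set.seed(55)
  hits <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    if (flank_matches(random_seq(50), random_seq(50)) >= 25L) hits <- hits + 1L
  }
  # false-drop calibration: chance similarity must be uncommon
  expect_lte(hits / n, 0.10)
})

test_that("the representative maximizes summed local alignment scores", {
  set.seed(56)
  base <- random_seq(150)
  ch <- strsplit(base, "", fixed = TRUE)[[1]]
  pos <- sample(150, 22)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  far <- paste(ch, collapse = "")   # ~85% identity to base

  # A and B identical, C diverged: the identical pair wins, first by
  # coordinate order breaks the tie
  fam <- fam_with_flanks(replicate(3, random_seq(50)),
                         replicate(3, random_seq(50)))
  fam$body <- c(base, base, far)
  expect_identical(select_representative(fam), 1L)
  fam_rev <- fam
  fam_rev$body <- c(far, base, base)
  expect_identical(select_representative(fam_rev), 2L)

  # all identical: pure tie-break on (seq_id, start)
  fam$body <- rep(base, 3)
  expect_identical(select_representative(fam), 1L)
})

test_that("representative selection agrees with an exhaustive oracle", {
  set.seed(57)
  scoring <- mite_config()$local_scoring
  for (rep in 1:4) {
    k <- sample(3:5, 1)
    base <- random_seq(sample(80:140, 1))
    bodies <- vapply(seq_len(k), function(i) {
      ch <- strsplit(base, "", fixed = TRUE)[[1]]
      pos <- sample(length(ch), sample(0:15, 1))
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
    fam <- fam_with_flanks(replicate(k, random_seq(50)),
                           replicate(k, random_seq(50)))
    fam$body <- bodies
    # oracle: recompute every pairwise local score with the DP reference
    S <- matrix(0, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      S[i, j] <- S[j, i] <- sw_local_score(bodies[i], bodies[j])
    }
    totals <- rowSums(S)
    want <- which(totals == max(totals))[1]   # rows already in genomic order
    expect_identical(select_representative(fam, scoring), as.integer(want))
  }
})

test_that("finalize_families enforces the three-valid-member rule", {
  cfg <- mite_config()
  set.seed(58)
  pool <- draw_divergent_flanks(4)
  shared <- pool[1]
  dv <- pool[2:4]
  base <- random_seq(180)
  mk <- function(n, left, fid) {
    fam <- fam_with_flanks(left, draw_divergent_flanks(n))
    fam$body <- rep(base, n)
    fam$family_id <- fid
    fam$is_seed <- seq_len(n) == 1L
    fam
  }
  # family of 5 reduced to 3 by flank filtration: retained
  f1 <- mk(5, c(shared, shared, dv[1], dv[2], shared), "FAM0001")
  # family of 3 reduced to 2: dropped
  f2 <- mk(3, c(shared, shared, dv[3]), "FAM0002")
  f2$start <- f2$start + 50000L; f2$end <- f2$end + 50000L
  # family of 3 with divergent flanks: retained unchanged
  f3 <- mk(3, draw_divergent_flanks(3), "FAM0003")
  f3$start <- f3$start + 100000L; f3$end <- f3$end + 100000L
  fams <- finalize_families(rbind(f1, f2, f3), cfg)
  expect_identical(sort(fams$families$family_id), c("FAM0001", "FAM0003"))
  expect_identical(fams$families$n_members[fams$families$family_id == "FAM0001"], 3L)
  audit <- fams$flank_audit
  expect_identical(audit$members_after[audit$family_id == "FAM0002"], 2L)
  expect_false(audit$retained[audit$family_id == "FAM0002"])
  # each retained family's representative is one of its members
  for (fid in fams$families$family_id) {
    mem <- fams$members[fams$members$family_id == fid, ]
    expect_identical(sum(mem$is_representative), 1L)
    rep_row <- mem[mem$is_representative, ]
    expect_true(rep_row$start %in% mem$start)
  }
})
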