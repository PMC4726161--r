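test_that("encoding follows the complex mapping and flags ambiguous bases", {
  e <- encode_sequence("ACGT")
  expect_identical(e$scores, c(1 + 0i, 0 + 1i, 0 - 1i, -1 + 0i))
  expect_equal(e$prefix[5] - e$prefix[1], 0 + 0i)

  e0 <- encode_sequence("")
  expect_identical(e0$n, 0L)
  expect_identical(e0$prefix, 0 + 0i)

  e2 <- encode_sequence("ANA")
  expect_identical(e2$valid, c(TRUE, FALSE, TRUE))
  # any window covering the invalid base is excluded
  cfg <- mite_config(tir_len = 2L, min_len = 4L, max_len = 4L)
  expect_identical(nrow(screen_tir_pairs(encode_sequence("ATNAT"), cfg)), 0L)
})

test_that("window sums equal prefix differences for arbitrary windows", {
  set.seed(21)
  for (rep in 1:20) {
    s <- random_seq(100)
    e <- encode_sequence(s)
    i <- sample(90, 1)
    w <- sample(10, 1)
    expect_equal(e$prefix[i + w] - e$prefix[i], complex_score(substr(s, i, i + w - 1)))
  }
})

test_that("a perfect TIR pair screens at C = 0 and verifies with 0 mismatches", {
  left <- "GGGCCCAAAT"
  right <- oracle_revcomp(left)
  set.seed(22)
  s <- paste0(left, random_seq(70), right)   # span 90
  cfg <- mite_config()
  pairs <- screen_tir_pairs(encode_sequence(s), cfg)
  expect_true(any(pairs$left_start == 1L & pairs$right_start == 81L))
  v <- verify_tir(s, 1L, 81L, 10L, 1L)
  expect_true(v$accepted)
  expect_identical(v$mismatches, 0L)
})

test_that("every single-arm substitution shifts the screen statistic to exactly 2", {
  set.seed(23)
  for (rep in 1:5) {
    left <- random_seq(10)
    right0 <- oracle_revcomp(left)
    for (p in 1:10) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(right0, p, p))) {
        right <- right0
        substr(right, p, p) <- b
        C <- complex_score(left) + complex_score(right)
        expect_equal(l1_norm(C), 2)
        v <- verify_tir(paste0(left, right), 1L, 11L, 10L, 1L)
        expect_true(v$accepted)
        expect_identical(v$mismatches, 1L)
      }
    }
  }
})

# build an arm pair with compensating A<->A and T<->T mismatches at
# symmetric positions: C = 0 but two positions are non-complementary
compensating_pair <- function() {
  repeat {
    left <- random_seq(10)
    p <- sample(9, 1)
    substr(left, p, p) <- "A"
    substr(left, 11 - p, 11 - p) <- "T"
    right <- oracle_revcomp(left)
    substr(right, 11 - p, 11 - p) <- "A"   # partner of left A -> A:A pair
    substr(right, p, p) <- "T"             # partner of left T -> T:T pair
    return(list(left = left, right = right))
  }
}

test_that("compensating double mismatches pass the screen but fail verification", {
  set.seed(24)
  for (rep in 1:10) {
    arms <- compensating_pair()
    C <- complex_score(arms$left) + complex_score(arms$right)
    expect_equal(l1_norm(C), 0)
    s <- paste0(arms$left, strrep("A", 40), arms$right)  # span 60
    cfg <- mite_config()
    pairs <- screen_tir_pairs(encode_sequence(s), cfg)
    expect_true(any(pairs$left_start == 1L & pairs$right_start == 51L))
    v <- verify_tir(s, 1L, 51L, 10L, 1L)
    expect_false(v$accepted)
    expect_identical(v$mismatches, 2L)
  }
})

test_that("find_tsd returns the longest exact direct repeat, or nothing", {
  cfg <- mite_config()
  set.seed(25)
  body <- random_seq(60)
  # plant "TA" only
  s1 <- paste0("CCGG", "TA", body, "TA", "GGCC")
  expect_identical(find_tsd(s1, 7L, 66L, cfg), "TA")
  # both "TAG" and "TA"-like repeats qualify: the longest wins
  s2 <- paste0("CC", "TAG", body, "TAG", "GG")
  expect_identical(find_tsd(s2, 6L, 65L, cfg), "TAG")
  # no direct repeat at any length
  s3 <- paste0("CCCC", body, "GGGG")
  expect_identical(find_tsd(s3, 5L, 64L, cfg), NA_character_)
  # contig edge disqualifies lengths that run out of sequence
  s4 <- paste0("TA", body, "TA")
  expect_identical(find_tsd(s4, 3L, 62L, cfg), "TA")
})

test_that("scan recovers a planted element with exact boundaries", {
  cfg <- mite_config()
  set.seed(26)
  m <- make_mite(200, "TA", 0L, cfg)
  bg <- random_seq(5000)
  pos <- 2000L
  # "CCGG"/"GGCC" guards prevent any chance extension of the planted TSD
  s <- paste0(substr(bg, 1, pos), "CCGG", m$element, "GGCC",
              substr(bg, pos + 1, nchar(bg)))
  cands <- scan_chromosome(s, "chr1", cfg)
  hit <- cands[cands$start == pos + 7L & cands$end == pos + 206L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$tsd, "TA")
  expect_identical(hit$tir_mismatches, 0L)
  expect_identical(hit$body, m$body)
})

test_that("chunked and unchunked scans agree exactly", {
  set.seed(27)
  cfg_full <- mite_config()
  cfg_chunk <- mite_config(chunk_size = 1000L)
  m1 <- make_mite(150, "TA", 0L, cfg_full)
  m2 <- make_mite(300, "TAGC", 1L, cfg_full)
  s <- paste0(random_seq(900), m1$element, random_seq(800), m2$element,
              random_seq(1200))
  a <- scan_chromosome(s, "chr1", cfg_full)
  b <- scan_chromosome(s, "chr1", cfg_chunk)
  expect_identical(a, b)
  expect_true(nrow(a) >= 2L)
})

test_that("chromosomes shorter than the minimum element yield no candidates", {
  cfg <- mite_config()
  expect_identical(nrow(scan_chromosome(random_seq(30), "tiny", cfg)), 0L)
})

test_that("scan equals the brute-force structural scanner on random sequences", {
  cfg <- mite_config()
  set.seed(28)
  total <- 0L
  for (rep in 1:12) {
    n <- sample(500:1500, 1)
    alpha <- if (rep %% 4 == 0) c("A", "C", "G", "T", "N") else
      c("A", "C", "G", "T")
    s <- random_seq(n, alphabet = alpha)
    got <- scan_chromosome(s, "x", cfg)
    want <- brute_scan_oracle(s, cfg)
    expect_identical(cand_key(got), cand_key(want))
    total <- total + nrow(want)
  }
  expect_gt(total, 0L)  # the comparison must not be vacuous
})

test_that("reverse-complementing the genome mirrors candidates and TSDs", {
  cfg <- mite_config()
  set.seed(29)
  m <- make_mite(120, "TCA", 0L, cfg)
  s <- paste0(random_seq(600), m$element, random_seq(600))
  n <- nchar(s)
  fwd <- scan_chromosome(s, "x", cfg)
  rev <- scan_chromosome(oracle_revcomp(s), "x", cfg)
  mirrored <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L,
                         tsd = vapply(rev$tsd, oracle_revcomp, character(1),
                                      USE.NAMES = FALSE))
  expect_identical(cand_key(fwd),
                   cand_key(mirrored))
})
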