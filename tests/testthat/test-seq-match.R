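test_that("normalization folds case, maps U to T and rejects ambiguity codes", {
  expect_equal(normalize_seq("uagUUGGU"), "TAGTTGGT")
  expect_equal(normalize_seq("UAGUUGGUGGAGCGAUUUGUC"),
               "TAGTTGGTGGAGCGATTTGTC")
  expect_equal(normalize_seq(" AC GT\n"), "ACGT")
  expect_error(normalize_seq("ACGN"), "position 4")
  expect_error(normalize_seq("ACG-T"), "position 4")
  expect_error(normalize_seq("   "), "Empty sequence")
})

test_that("exact search finds all full-length occurrences on both strands", {
  hit <- exact_search("ACGT", "TTACGTTT")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ref_start, 2L)
  expect_equal(hit$ref_end, 6L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$category, "EXACT_FULL")

  self <- exact_search("ACGTAC", "ACGTAC")
  expect_equal(self$ref_start, 0L)
  expect_equal(self$ref_end, 6L)

  # antisense occurrence reported in forward coordinates with strand "-"
  anti <- exact_search("AACCG", paste0("TT", revcomp("AACCG"), "TT"))
  expect_equal(anti$strand, "-")
  expect_equal(anti$ref_start, 2L)
  expect_equal(anti$ref_end, 7L)

  # planted candidate between random flanks: exactly one hit, where planted
  withr::with_seed(11L, {
    cand <- normalize_seq("UAGUUGGUGGAGCGAUUUGUC")
    left <- random_seq(80L)
    ref <- paste0(left, cand, random_seq(80L))
    hits <- exact_search(cand, ref)
    expect_equal(hits$ref_start, oracle_exact_starts(cand, ref))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$ref_start, nchar(left))
  })

  expect_error(exact_search("ACGTACGT", "ACGT"), "longer than")
})

test_that("longest perfect stretch matches a substring-containment oracle", {
  cfg <- match_config()
  planted <- longest_perfect_stretch(
    paste0("AAAAA", "CGTCAGTCGATCGAT", "A"),
    paste0("TTTTTT", "CGTCAGTCGATCGAT", "GGGGGG"), cfg)
  expect_equal(planted$category, "PARTIAL")
  expect_gte(planted$matched_length, 15L)

  below <- longest_perfect_stretch("ACGTACGTAC TTTTTTTTTT",
                                   "ACGTACGTACCCCCAAAAAAAAAA", cfg)
  expect_equal(below$category, "NONE")
  expect_true(is.na(below$ref_start))

  withr::with_seed(21L, {
    for (i in 1:40) {
      cand <- random_seq(21L)
      ref <- random_seq(sample(200:600, 1L))
      got <- longest_perfect_stretch(cand, ref, cfg)
      expect_equal(got$matched_length, oracle_lcs_len(cand, ref),
                   info = paste("trial", i))
    }
  })
})

test_that("windowed matching returns the minimum-mismatch window", {
  cfg <- match_config()
  withr::with_seed(31L, {
    cand <- random_seq(20L)
    ref <- paste0(random_seq(50L), cand, random_seq(50L))
    exact <- best_windowed_match(cand, ref, cfg)
    expect_equal(exact$category, "EXACT_FULL")
    expect_equal(exact$mismatches, 0L)
    expect_equal(exact$ref_start, 50L)

    # plant with exactly one substitution
    mut <- paste0(substr(cand, 1L, 9L),
                  setdiff(c("A", "C", "G", "T"),
                          substr(cand, 10L, 10L))[1L],
                  substr(cand, 11L, 20L))
    near <- best_windowed_match(cand, paste0(random_seq(40L), mut,
                                             random_seq(40L)), cfg)
    expect_equal(near$category, "NEAR")
    expect_equal(near$mismatches, 1L)
  })

  # random instances vs the exhaustive all-window oracle
  withr::with_seed(32L, {
    for (i in 1:40) {
      cand <- random_seq(sample(15:25, 1L))
      ref <- random_seq(sample(100:400, 1L))
      got <- best_windowed_match(cand, ref, cfg)
      expect_equal(got$mismatches, as.integer(oracle_min_hamming(cand, ref)),
                   info = paste("trial", i))
    }
  })
})

test_that("an exact windowed hit is confirmed by exact search at the same place", {
  cfg <- match_config()
  withr::with_seed(41L, {
    for (i in 1:20) {
      cand <- random_seq(18L)
      ref <- paste0(random_seq(30L), cand, random_seq(30L))
      wm <- best_windowed_match(cand, ref, cfg)
      expect_equal(wm$category, "EXACT_FULL")
      es <- exact_search(cand, ref, cfg)
      expect_true(any(es$ref_start == wm$ref_start &
                        es$strand == wm$strand))
    }
  })
})

test_that("match categories are symmetric under reverse complement", {
  cfg <- match_config()
  withr::with_seed(51L, {
    for (i in 1:20) {
      cand <- random_seq(20L)
      ref <- if (i %% 2L) paste0(random_seq(60L), cand, random_seq(60L))
             else random_seq(200L)
      a <- classify_host_match(cand, c(ref1 = ref), cfg)
      b <- classify_host_match(revcomp(cand), c(ref1 = ref), cfg)
      expect_equal(a$category, b$category, info = paste("trial", i))
    }
  })
})

test_that("loosening match thresholds never downgrades a category", {
  rank_of <- function(cat) {
    match(cat, c("NONE", "PARTIAL", "NEAR", "EXACT_FULL"))
  }
  withr::with_seed(61L, {
    for (i in 1:15) {
      cand <- random_seq(20L)
      # plant a 1-mismatch copy in some trials so NEAR actually arises
      ref <- if (i %% 3L == 0L) {
        mut <- paste0(substr(cand, 1L, 9L),
                      setdiff(c("A", "C", "G", "T"),
                              substr(cand, 10L, 10L))[1L],
                      substr(cand, 11L, 20L))
        paste0(random_seq(140L), mut, random_seq(140L))
      } else {
        random_seq(300L)
      }
      near1 <- best_windowed_match(cand, ref, match_config())
      near3 <- best_windowed_match(cand, ref,
                                   match_config(near_max_mismatches = 3))
      expect_gte(rank_of(near3$category), rank_of(near1$category))
      p15 <- longest_perfect_stretch(cand, ref, match_config())
      p8 <- longest_perfect_stretch(
        cand, ref, match_config(partial_min_stretch = 8))
      expect_gte(rank_of(p8$category), rank_of(p15$category))
    }
  })
})

test_that("containment reports the first forward-strand offset", {
  nested <- seq_contains("UCUACUCGACCUGGUGGUCGAGUGGU",
                         "CUCGACCUGGUGGUCGAGUGGU")
  expect_true(nested$contained)
  expect_equal(nested$offset, 4L)

  self <- seq_contains("ACGTACGT", "ACGTACGT")
  expect_true(self$contained)
  expect_equal(self$offset, 0L)

  expect_false(seq_contains("ACGT", "ACGTA")$contained)
})

test_that("host-match classification applies the category precedence", {
  cfg <- match_config()
  withr::with_seed(71L, {
    cand <- random_seq(21L)
    ref_partial <- paste0(random_seq(40L), substr(cand, 3L, 18L),
                          random_seq(40L))
    ref_exact <- paste0(random_seq(40L), cand, random_seq(40L))
    best <- classify_host_match(
      cand, c(frag_ref = ref_partial, full_ref = ref_exact), cfg)
    expect_equal(best$category, "EXACT_FULL")
    expect_equal(best$reference_id, "full_ref")

    # nothing shared: NONE with no coordinates
    none <- classify_host_match("ACGTACGTACGTACGTACGT",
                                c(r = paste(rep("A", 100L), collapse = "")),
                                cfg)
    expect_equal(none$category, "NONE")
    expect_true(is.na(none$ref_start))
  })
})
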