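test_that("replicate runs are summed into library counts and incomplete libraries dropped", {
  counts <- tibble::tibble(
    candidate_id = rep(c("mirA", "mirB"), each = 5L),
    sample_id = rep(c("L1_r1", "L1_r2", "L2_r1", "L2_r2", "L3_r1"), 2L),
    count = c(5L, 7L, 3L, 4L, 9L, 0L, 1L, 2L, 2L, 8L)
  )
  meta <- tibble::tibble(
    sample_id = c("L1_r1", "L1_r2", "L2_r1", "L2_r2", "L3_r1"),
    library_id = c("L1", "L1", "L2", "L2", "L3"),
    study = "s", sample_type = "plasma",
    total_reads = c(10, 20, 30, 40, 50)
  )
  merged <- merge_replicate_runs(counts, meta)
  expect_setequal(unique(merged$counts$sample_id), c("L1", "L2"))
  expect_equal(
    merged$counts$count[merged$counts$candidate_id == "mirA" &
                          merged$counts$sample_id == "L1"], 12L)
  expect_equal(merged$meta$total_reads[merged$meta$sample_id == "L1"], 30)

  # keeping incomplete libraries preserves them as single-run columns
  kept <- merge_replicate_runs(counts, meta, drop_incomplete = FALSE)
  expect_setequal(unique(kept$counts$sample_id), c("L1", "L2", "L3"))

  # single-run-per-library input is passed through unchanged
  single <- dplyr::filter(counts, grepl("_r1$", sample_id))
  merged_single <- merge_replicate_runs(single,
                                        dplyr::filter(meta,
                                                      grepl("_r1$", sample_id)))
  expect_equal(sum(merged_single$counts$count), sum(single$count))
  expect_equal(dplyr::n_distinct(merged_single$counts$sample_id), 3L)

  expect_error(
    merge_replicate_runs(counts, dplyr::filter(meta, sample_id != "L3_r1")),
    "missing from metadata")
})

test_that("merging conserves total reads over retained libraries", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      counts <- random_count_tbl(8L, 12L, lambda = 5)
      meta <- tibble::tibble(
        sample_id = sprintf("s%03d", 1:12),
        library_id = rep(sprintf("L%d", 1:6), each = 2L),
        study = "s", sample_type = "plasma", total_reads = NA_real_
      )
      merged <- merge_replicate_runs(counts, meta)
      expect_equal(sum(merged$counts$count), sum(counts$count))
    })
  }
})

test_that("rpm translation is linear and inverts estimate_rpm", {
  cfg <- screen_config()
  expect_equal(reads_for_rpm_cutoff(cfg, mapping_fraction = 0.5), 200)
  expect_equal(reads_for_rpm_cutoff(screen_config(rpm_cutoff = 64),
                                    mapping_fraction = 0.5), 400)
  expect_equal(
    reads_for_rpm_cutoff(screen_config(rpm_cutoff = 1e-9),
                         mapping_fraction = 0.5),
    1e-9 * 12.5e6 * 0.5 / 1e6)
  expect_equal(estimate_rpm(0, cfg), 0)
  # round trip at the config's own mapping fraction
  for (seed in 1:10) {
    withr::with_seed(seed, {
      cfg <- screen_config(rpm_cutoff = runif(1, 1, 100),
                           mean_reads_per_sample = runif(1, 1e6, 5e7),
                           mapping_fraction = runif(1, 0.1, 1))
      reads <- reads_for_rpm_cutoff(cfg,
                                    mapping_fraction = cfg$mapping_fraction)
      expect_equal(estimate_rpm(reads, cfg), cfg$rpm_cutoff)
    })
  }
})

test_that("candidate summaries match a brute-force recomputation", {
  counts <- tibble::tibble(
    candidate_id = "m", sample_id = sprintf("s%d", 1:4),
    count = c(1L, 2L, 3L, 4L)
  )
  s <- summarize_candidate(counts, "m")
  expect_equal(s$n_samples_min_reads, 2L)
  expect_equal(s$mean_counts, 2.5)
  expect_equal(s$median_counts, 2.5)
  expect_equal(s$max_counts, 4L)

  zero <- dplyr::mutate(counts, count = 0L)
  sz <- summarize_candidate(zero, "m")
  expect_equal(sz[c("n_samples_min_reads", "mean_counts", "median_counts",
                    "max_counts")],
               tibble::tibble(n_samples_min_reads = 0L, mean_counts = 0,
                              median_counts = 0, max_counts = 0L))

  expect_error(summarize_candidate(counts, "nope"), "Unknown candidate")

  # brute force over random matrices
  cfg <- screen_config()
  for (seed in 1:3) {
    withr::with_seed(seed, {
      tbl <- random_count_tbl(25L, 60L)
      s <- summarize_candidates(tbl, cfg)
      wide <- tidyr::pivot_wider(tbl, names_from = sample_id,
                                 values_from = count)
      mat <- as.matrix(wide[-1L])
      expected <- tibble::tibble(
        candidate_id = wide$candidate_id,
        n = apply(mat, 1L, function(x) sum(x >= 3)),
        mean = apply(mat, 1L, mean),
        med = apply(mat, 1L, function(x) median(sort(x))),
        max = apply(mat, 1L, max)
      )
      got <- s[match(expected$candidate_id, s$candidate_id), ]
      expect_equal(got$n_samples_min_reads, expected$n)
      expect_equal(got$mean_counts, expected$mean)
      expect_equal(got$median_counts, expected$med)
      expect_equal(got$max_counts, expected$max)
    })
  }
})

test_that("inclusion screen uses a ceiling threshold and the annotation set", {
  counts <- tibble::tibble(
    candidate_id = rep(c("hit", "miss"), each = 10L),
    sample_id = rep(sprintf("s%02d", 1:10), 2L),
    count = c(3L, rep(0L, 9L), rep(2L, 10L))
  )
  # 10% of 10 samples -> ceiling gives 1 sample; one qualifying sample is
  # enough
  inc <- inclusion_screen(counts)
  expect_equal(inc$candidate_id, "hit")
  # candidate meeting the count criteria but not annotated is excluded
  expect_equal(nrow(inclusion_screen(counts, annotated = "miss")), 0L)
  expect_equal(nrow(inclusion_screen(counts, annotated = character(0L))), 0L)
})

test_that("relaxing inclusion thresholds never removes candidates", {
  withr::with_seed(42L, {
    tbl <- random_count_tbl(20L, 40L, lambda = 1.5)
    base <- inclusion_screen(tbl, screen_config())$candidate_id
    looser_reads <- inclusion_screen(tbl, screen_config(min_reads = 2))
    looser_frac <- inclusion_screen(
      tbl, screen_config(min_sample_fraction = 0.05))
    expect_true(all(base %in% looser_reads$candidate_id))
    expect_true(all(base %in% looser_frac$candidate_id))
  })
})

test_that("background screen is strictly above the median cutoff", {
  summaries <- tibble::tibble(
    candidate_id = c("a", "b", "c"),
    median_counts = c(199, 200, 201)
  )
  expect_equal(background_screen(summaries)$candidate_id, "c")
  expect_equal(nrow(background_screen(
    dplyr::mutate(summaries, median_counts = 0))), 0L)
})

test_that("background-screen hits are a subset of the inclusion screen", {
  withr::with_seed(7L, {
    tbl <- random_count_tbl(10L, 30L, lambda = 3)
    tbl$count[tbl$candidate_id == "c01"] <-
      rpois(30L, 400)  # one abundant candidate
    summaries <- summarize_candidates(tbl)
    above <- background_screen(summaries)$candidate_id
    included <- inclusion_screen(tbl)$candidate_id
    expect_true(all(above %in% included))
  })
})

test_that("sample-type subsets keep all candidate rows", {
  counts <- tibble::tibble(
    candidate_id = rep(c("m1", "m2"), each = 23L),
    sample_id = rep(sprintf("s%02d", 1:23), 2L),
    count = c(rep(1L, 23L), rep(0L, 23L))
  )
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:23),
    library_id = sprintf("s%02d", 1:23),
    study = "mixed",
    sample_type = c(rep("cell", 17L), rep("plasma", 6L)),
    total_reads = NA_real_
  )
  plasma <- subset_by_sample_type(counts, meta, "plasma")
  expect_equal(dplyr::n_distinct(plasma$sample_id), 6L)
  # all-zero candidate retained
  expect_setequal(unique(plasma$candidate_id), c("m1", "m2"))
  # restricting to the only type present is the identity
  all_cells <- subset_by_sample_type(
    counts, dplyr::mutate(meta, sample_type = "cell"), "cell")
  expect_equal(dplyr::arrange(all_cells, candidate_id, sample_id),
               dplyr::arrange(validate_counts(counts), candidate_id,
                              sample_id))
  expect_error(subset_by_sample_type(counts, meta, "other"), "No sample")
})
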