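test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(seed = 5L, n_libraries = 12L, n_candidates = 6L,
                    n_reads = 40L)
  a <- simulate_count_study(cfg)
  b <- simulate_count_study(cfg)
  expect_identical(a, b)
  ra <- simulate_references(cfg)
  rb <- simulate_references(cfg)
  expect_identical(ra, rb)
  expect_identical(simulate_reads(cfg, ra)$reads,
                   simulate_reads(cfg, rb)$reads)
  # a different seed changes the draw
  expect_false(identical(
    a$counts,
    simulate_count_study(sim_config(seed = 6L, n_libraries = 12L,
                                    n_candidates = 6L))$counts))
})

test_that("run-level counts conserve library totals and merge back exactly", {
  cfg <- sim_config(seed = 9L, n_libraries = 30L, n_candidates = 8L,
                    n_incomplete_libraries = 2L)
  sim <- simulate_count_study(cfg)
  run_totals <- sim$counts |>
    dplyr::inner_join(dplyr::select(sim$meta, sample_id, library_id),
                      by = "sample_id") |>
    dplyr::group_by(candidate_id, library_id) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  truth <- dplyr::rename(sim$truth$library_counts, library_id = sample_id)
  joined <- dplyr::inner_join(run_totals, truth,
                              by = c("candidate_id", "library_id"),
                              suffix = c("_run", "_lib"))
  expect_equal(joined$count_run, joined$count_lib)

  merged <- merge_replicate_runs(sim$counts, sim$meta)
  expect_equal(dplyr::n_distinct(merged$counts$sample_id), 28L)
  remerged <- dplyr::inner_join(merged$counts, truth,
                                by = c("candidate_id",
                                       "sample_id" = "library_id"),
                                suffix = c("_m", "_t"))
  expect_equal(remerged$count_m, remerged$count_t)
})

test_that("a zero background rate leaves only host-derived candidates", {
  cfg <- sim_config(seed = 3L, n_libraries = 40L, n_candidates = 10L,
                    n_host_derived = 2L, background_rate = 0,
                    n_incomplete_libraries = 0L)
  sim <- simulate_count_study(cfg)
  merged <- merge_replicate_runs(sim$counts, sim$meta)
  host_ids <- sim$truth$candidates$candidate_id[
    sim$truth$candidates$true_class == "host_derived"]
  background <- dplyr::filter(merged$counts,
                              !candidate_id %in% host_ids)
  expect_true(all(background$count == 0L))
  inc <- inclusion_screen(merged$counts)
  expect_setequal(inc$candidate_id, host_ids)
})

test_that("planted reference regions realize their configured match level", {
  cfg <- sim_config(seed = 13L, n_candidates = 8L,
                    match_levels = c("exact", "partial15", "near1", "none"))
  refs <- simulate_references(cfg)
  got <- classify_host_matches(refs$candidates, refs$host)
  level_of <- refs$truth$level[match(got$candidate_id,
                                     refs$truth$candidate_id)]
  expect_equal(got$category[level_of == "exact"],
               rep("EXACT_FULL", sum(level_of == "exact")))
  near <- got[level_of == "near1", ]
  expect_equal(near$category, rep("NEAR", nrow(near)))
  expect_equal(near$mismatches, rep(1L, nrow(near)))
  expect_equal(got$category[level_of == "partial15"],
               rep("PARTIAL", sum(level_of == "partial15")))
  expect_equal(got$category[level_of == "none"],
               rep("NONE", sum(level_of == "none")))
  # planted coordinates are where the exact copies actually sit
  exact_truth <- dplyr::filter(refs$truth, level == "exact")
  for (i in seq_len(nrow(exact_truth))) {
    cand <- refs$candidates$seq[refs$candidates$id ==
                                  exact_truth$candidate_id[i]]
    ref <- refs$host$seq[refs$host$id == exact_truth$host_reference[i]]
    hits <- exact_search(cand, ref)
    expect_true(exact_truth$planted_start[i] %in% hits$ref_start)
  }
})

test_that("simulated reads carry labels consistent with the filter", {
  cfg <- sim_config(seed = 17L, n_candidates = 6L, n_reads = 200L,
                    match_levels = c("exact", "none", "none"))
  rr <- simulate_reads(cfg)
  run <- filter_reads(rr$reads, rr$refs$host, rr$refs$foreign,
                      filter_config(host_max_mismatches =
                                      cfg$host_read_max_mismatches))
  origin <- table(rr$reads$origin)
  s <- run$summary
  n <- function(cat) s$n[s$category == cat]
  expect_equal(n("host_removed"), unname(origin[["host"]]))
  expect_equal(n("unassigned"), unname(origin[["noise"]]))
  expect_equal(n("foreign_assigned") + n("ambiguous"),
               unname(origin[["foreign"]]))

  # all-host mixtures are removed wholesale
  all_host <- simulate_reads(sim_config(seed = 19L, n_candidates = 4L,
                                        n_reads = 50L,
                                        fraction_host_reads = 1,
                                        fraction_foreign_reads = 0))
  res <- host_subtract(all_host$reads, all_host$refs$host)
  expect_equal(nrow(res$retained), 0L)

  empty <- simulate_reads(sim_config(seed = 23L, n_reads = 0L))
  expect_equal(nrow(empty$reads), 0L)
})
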