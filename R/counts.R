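#' Validate a long count table
#'
#' The package represents a candidate-by-sample count matrix as a long
#' tibble with columns `candidate_id`, `sample_id` and `count` (integer
#' total mapped reads). Candidates absent from a sample are rows with
#' count 0, never missing rows; [read_count_table()] and the simulators
#' produce complete tables.
#'
#' @param counts A data frame with columns `candidate_id`, `sample_id`,
#'   `count`.
#' @return The validated counts as a tibble (invisibly usable in pipes).
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("candidate_id", "sample_id", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    abort(paste0("Count table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(counts$count)) abort("Counts must not be missing.")
  if (!is.numeric(counts$count) || any(counts$count < 0) ||
      any(counts$count != trunc(counts$count))) {
    abort("Counts must be non-negative integers.")
  }
  if (anyDuplicated(counts[c("candidate_id", "sample_id")])) {
    abort("Duplicated (candidate_id, sample_id) pair in count table.")
  }
  counts$count <- as.integer(counts$count)
  counts
}

#' Validate sample metadata
#'
#' @param meta A data frame with columns `sample_id`, `library_id`,
#'   `study`, `sample_type` (one of `plasma`, `cell`, `other`) and
#'   optionally `total_reads` (reads sequenced in that sample; `NA`
#'   allowed).
#' @return The validated metadata as a tibble.
#' @export
validate_sample_meta <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "library_id", "study", "sample_type")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Sample metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("Duplicated sample_id in metadata.")
  }
  bad <- setdiff(unique(meta$sample_type), sample_types())
  if (length(bad)) {
    abort(paste0("Unknown sample_type value(s): ",
                 paste(bad, collapse = ", "),
                 " (allowed: ", paste(sample_types(), collapse = ", "), ")"))
  }
  if (!"total_reads" %in% names(meta)) meta$total_reads <- NA_real_
  meta
}

#' Combine duplicate sequencing runs into library-level counts
#'
#' Libraries sequenced in several runs are merged by summing raw counts
#' (runs were repeated to increase total reads, so summation, not
#' averaging, is the faithful combination). Libraries with fewer than the
#' modal number of runs lack a reliable replicate and are dropped when
#' `drop_incomplete = TRUE`; with the default study design this turns 192
#' sequenced libraries into 190 retained ones.
#'
#' @param counts Long count table (see [validate_counts()]); one column of
#'   counts per sequencing run.
#' @param meta Sample metadata mapping each run (`sample_id`) to its
#'   `library_id`.
#' @param drop_incomplete Drop libraries with fewer runs than the modal
#'   number of runs per library?
#' @return A list with `counts` (long table whose `sample_id` is now the
#'   library id) and `meta` (library-level metadata; `total_reads` summed
#'   over runs).
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   candidate_id = "cand1", sample_id = c("L1a", "L1b"), count = c(5L, 7L)
#' )
#' meta <- tibble::tibble(
#'   sample_id = c("L1a", "L1b"), library_id = "L1",
#'   study = "s", sample_type = "plasma"
#' )
#' merge_replicate_runs(counts, meta)$counts
merge_replicate_runs <- function(counts, meta, drop_incomplete = TRUE) {
  counts <- validate_counts(counts)
  meta <- validate_sample_meta(meta)
  unknown <- setdiff(unique(counts$sample_id), meta$sample_id)
  if (length(unknown)) {
    abort(paste0("Sample(s) in count table missing from metadata: ",
                 paste(head(unknown, 5L), collapse = ", ")))
  }
  runs <- meta |>
    distinct(.data$sample_id, .data$library_id) |>
    count(.data$library_id, name = "n_runs")
  modal_runs <- as.integer(names(sort(table(runs$n_runs),
                                      decreasing = TRUE))[1L])
  keep <- if (drop_incomplete) {
    runs$library_id[runs$n_runs >= modal_runs]
  } else {
    runs$library_id
  }
  if (!length(keep)) abort("No library retained after replicate exclusion.")

  merged <- counts |>
    inner_join(select(meta, "sample_id", "library_id"), by = "sample_id") |>
    filter(.data$library_id %in% keep) |>
    group_by(.data$candidate_id, .data$library_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    rename(sample_id = "library_id") |>
    arrange(.data$candidate_id, .data$sample_id)
  if (!nrow(merged)) abort("No library retained after replicate exclusion.")

  lib_meta <- meta |>
    filter(.data$library_id %in% keep) |>
    group_by(.data$library_id) |>
    summarise(
      study = .data$study[1L],
      sample_type = .data$sample_type[1L],
      total_reads = if (anyNA(.data$total_reads)) NA_real_
                    else sum(.data$total_reads),
      .groups = "drop"
    ) |>
    rename(sample_id = "library_id") |>
    mutate(library_id = .data$sample_id, .after = "sample_id")

  list(counts = merged, meta = lib_meta)
}

#' Translate an rpm cutoff into raw mapped reads
#'
#' Converts a reads-per-million cutoff into the corresponding raw
#' mapped-read count in the average sample:
#' `rpm_cutoff * mean_reads_per_sample * mapping_fraction / 1e6`.
#' With the 32 rpm cutoff, 12.5 million reads per sample and about half of
#' the reads mapping, the cutoff translates to around 200 mapped reads.
#'
#' @param cfg A [screen_config()].
#' @param mapping_fraction Mapping fraction used for the translation; by
#'   default the coarse "about half mapped" value 0.5 rather than the
#'   back-derived `cfg$mapping_fraction`, so both constants are always
#'   explicit at the call site.
#' @return Raw mapped reads (double).
#' @export
#' @examples
#' reads_for_rpm_cutoff(screen_config(), mapping_fraction = 0.5) # 200
reads_for_rpm_cutoff <- function(cfg = screen_config(),
                                 mapping_fraction = 0.5) {
  stopifnot_scalar_num(mapping_fraction, "mapping_fraction",
                       lower = 0, upper = 1, lower_open = TRUE)
  cfg$rpm_cutoff * cfg$mean_reads_per_sample * mapping_fraction / 1e6
}

#' Estimate rpm from a raw mapped-read count
#'
#' Inverse of [reads_for_rpm_cutoff()]:
#' `count / (mean_reads_per_sample * mapping_fraction) * 1e6`, i.e. the
#' expression in reads per million mapped reads of a candidate with `count`
#' mapped reads in the average sample. With the default constants
#' (12.5e6 reads, mapping fraction 0.475) a median of 115 mapped reads
#' corresponds to 19.4 rpm and a median of 9 to 1.5 rpm.
#'
#' @param count Raw mapped-read count(s), >= 0. Vectorized.
#' @param cfg A [screen_config()].
#' @param mapping_fraction Mapping fraction; defaults to
#'   `cfg$mapping_fraction`.
#' @return Estimated rpm (double, full precision; round for display).
#' @export
#' @examples
#' round(estimate_rpm(c(115, 9, 1072.5)), 1)
estimate_rpm <- function(count, cfg = screen_config(),
                         mapping_fraction = cfg$mapping_fraction) {
  if (any(count < 0, na.rm = TRUE)) abort("`count` must be >= 0.")
  stopifnot_scalar_num(mapping_fraction, "mapping_fraction",
                       lower = 0, upper = 1, lower_open = TRUE)
  count / (cfg$mean_reads_per_sample * mapping_fraction) * 1e6
}

#' Per-candidate summary statistics
#'
#' For every candidate in the count table, computes the number of samples
#' with at least `cfg$min_reads` mapped reads, the mean, median and maximum
#' count over all samples (the median of an even number of samples is the
#' mean of the two central values, so half-integers are expected), and the
#' estimated median rpm via [estimate_rpm()]. When `meta` supplies per-
#' sample `total_reads`, an average rpm over samples
#' (`mean(count / total_reads * 1e6)`) is added; it uses total sequenced
#' reads, not mapped reads.
#'
#' @param counts Long count table.
#' @param cfg A [screen_config()].
#' @param meta Optional sample metadata with `total_reads`.
#' @return A tibble with one row per candidate, ordered by
#'   `n_samples_min_reads` (descending), then mean (descending), then
#'   candidate id.
#' @export
summarize_candidates <- function(counts, cfg = screen_config(), meta = NULL) {
  counts <- complete_counts(validate_counts(counts))
  if (!is.null(meta)) {
    meta <- validate_sample_meta(meta)
    counts <- left_join(counts, select(meta, "sample_id", "total_reads"),
                        by = "sample_id")
  } else {
    counts$total_reads <- NA_real_
  }
  counts |>
    group_by(.data$candidate_id) |>
    summarise(
      n_samples_min_reads = sum(.data$count >= cfg$min_reads),
      mean_counts = mean(.data$count),
      median_counts = median(.data$count),
      max_counts = max(.data$count),
      avg_rpm = if (anyNA(.data$total_reads)) NA_real_
                else mean(.data$count / .data$total_reads * 1e6),
      .groups = "drop"
    ) |>
    mutate(est_median_rpm = estimate_rpm(.data$median_counts, cfg),
           .before = "avg_rpm") |>
    arrange(desc(.data$n_samples_min_reads), desc(.data$mean_counts),
            .data$candidate_id)
}

#' Summarize a single candidate
#'
#' Convenience wrapper around [summarize_candidates()] for one candidate.
#'
#' @inheritParams summarize_candidates
#' @param candidate_id Candidate to summarize; must be present.
#' @return A one-row tibble.
#' @export
summarize_candidate <- function(counts, candidate_id,
                                cfg = screen_config(), meta = NULL) {
  counts <- validate_counts(counts)
  if (!candidate_id %in% counts$candidate_id) {
    abort(paste0("Unknown candidate: ", candidate_id))
  }
  out <- summarize_candidates(counts, cfg = cfg, meta = meta)
  filter(out, .data$candidate_id == !!candidate_id)
}

#' Permissive inclusion screen
#'
#' Retains candidates with at least `cfg$min_reads` mapped reads in at
#' least `ceiling(cfg$min_sample_fraction * n_samples)` samples whose
#' putative mature sequence is discoverable (i.e. whose id is in
#' `annotated`). The ceiling matters: with 23 samples the 10% criterion
#' demands 3 samples.
#'
#' @param counts Long count table.
#' @param cfg A [screen_config()].
#' @param annotated Character vector of candidate ids with a discoverable
#'   mature sequence; `NULL` treats every candidate as annotated. An empty
#'   vector yields an empty result.
#' @return A tibble of included candidates (summary columns), ordered by
#'   prevalence then mean then id.
#' @export
inclusion_screen <- function(counts, cfg = screen_config(), annotated = NULL) {
  counts <- validate_counts(counts)
  if (!nrow(counts)) abort("Count table is empty.")
  n_samples <- n_distinct(counts$sample_id)
  summaries <- summarize_candidates(counts, cfg = cfg)
  inclusion_from_summaries(summaries, n_samples, cfg = cfg,
                           annotated = annotated)
}

#' Inclusion screen from precomputed summaries
#'
#' Applies the prevalence criterion of [inclusion_screen()] to per-candidate
#' summaries, useful when only published summary statistics are available
#' rather than the underlying per-sample counts.
#'
#' @param summaries Tibble from [summarize_candidates()] (needs
#'   `candidate_id` and `n_samples_min_reads`).
#' @param n_samples Number of samples the summaries were computed over.
#' @inheritParams inclusion_screen
#' @return The included subset of `summaries`, ordered.
#' @export
inclusion_from_summaries <- function(summaries, n_samples,
                                     cfg = screen_config(),
                                     annotated = NULL) {
  summaries <- as_tibble(summaries)
  threshold <- ceiling(cfg$min_sample_fraction * n_samples)
  out <- filter(summaries, .data$n_samples_min_reads >= threshold)
  if (!is.null(annotated)) {
    out <- filter(out, .data$candidate_id %in% annotated)
  }
  if ("mean_counts" %in% names(out)) {
    out <- arrange(out, desc(.data$n_samples_min_reads),
                   desc(.data$mean_counts), .data$candidate_id)
  } else {
    out <- arrange(out, desc(.data$n_samples_min_reads), .data$candidate_id)
  }
  out
}

#' Background screen on median counts
#'
#' Candidates whose median mapped-read count strictly exceeds
#' `cfg$background_median_reads` ("above a median 200 read cutoff";
#' boundary equality is excluded).
#'
#' @param summaries Tibble from [summarize_candidates()].
#' @param cfg A [screen_config()].
#' @return The above-background subset of `summaries`.
#' @export
background_screen <- function(summaries, cfg = screen_config()) {
  summaries <- as_tibble(summaries)
  filter(summaries, .data$median_counts > cfg$background_median_reads)
}

#' Restrict a count table to one sample type
#'
#' Keeps only the samples of the requested type; every candidate row is
#' retained (as zeros where needed) so downstream summaries stay comparable.
#'
#' @param counts Long count table.
#' @param meta Sample metadata.
#' @param sample_type One of `plasma`, `cell`, `other`.
#' @return The restricted long count table.
#' @export
subset_by_sample_type <- function(counts, meta, sample_type) {
  counts <- validate_counts(counts)
  meta <- validate_sample_meta(meta)
  if (!sample_type %in% sample_types()) {
    abort(paste0("Unknown sample_type: ", sample_type))
  }
  keep <- meta$sample_id[meta$sample_type == sample_type]
  keep <- intersect(unique(counts$sample_id), keep)
  if (!length(keep)) {
    abort(paste0("No sample of type '", sample_type, "' in the count table."))
  }
  candidates <- unique(counts$candidate_id)
  counts |>
    filter(.data$sample_id %in% keep) |>
    complete_counts(candidates = candidates, samples = keep)
}

# make a long count table complete over candidate x sample, filling 0
complete_counts <- function(counts, candidates = NULL, samples = NULL) {
  candidates <- candidates %||% unique(counts$candidate_id)
  samples <- samples %||% unique(counts$sample_id)
  tidyr::complete(
    counts,
    candidate_id = candidates,
    sample_id = samples,
    fill = list(count = 0L)
  )
}
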