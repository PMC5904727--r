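#' Count-screen configuration
#'
#' All thresholds and normalization constants used by the count-table
#' screening functions. Defaults reproduce the screening conditions of the
#' reanalysis the package implements: an expression cutoff of 32 reads per
#' million mapped reads (rpm), an inclusion criterion of at least 3 mapped
#' reads in at least 10% of samples, an average sequencing depth of
#' 12.5 million reads per sample, and a background cutoff of a median of
#' 200 mapped reads (roughly the 32 rpm cutoff at that depth).
#'
#' @param rpm_cutoff Expression cutoff in reads per million mapped reads.
#' @param min_reads Minimum per-sample mapped-read count for the inclusion
#'   screen.
#' @param min_sample_fraction Minimum fraction of samples in which
#'   `min_reads` must be reached; the sample threshold is the ceiling of
#'   `min_sample_fraction * n_samples`.
#' @param mean_reads_per_sample Average total reads sequenced per sample
#'   (used to convert counts to rpm).
#' @param mapping_fraction Fraction of sequenced reads that map, in (0, 1].
#'   The default 0.475 is the midpoint of the mapping-rate range of the
#'   large plasma cohort, back-derived so that [estimate_rpm()] reproduces
#'   the published estimated-median-rpm values; the coarser "about half
#'   mapped" value 0.5 is used by default in [reads_for_rpm_cutoff()], where
#'   it is an explicit argument.
#' @param background_median_reads Median mapped-read count above which a
#'   candidate is considered to exceed background (strict inequality).
#'
#' @return A list of class `xenomir_screen_config`.
#' @seealso [reads_for_rpm_cutoff()], [estimate_rpm()], [inclusion_screen()],
#'   [background_screen()]
#' @export
#' @examples
#' cfg <- screen_config()
#' reads_for_rpm_cutoff(cfg, mapping_fraction = 0.5)
screen_config <- function(rpm_cutoff = 32,
                          min_reads = 3L,
                          min_sample_fraction = 0.10,
                          mean_reads_per_sample = 12.5e6,
                          mapping_fraction = 0.475,
                          background_median_reads = 200) {
  stopifnot_scalar_num(rpm_cutoff, "rpm_cutoff", lower = 0)
  stopifnot_scalar_num(min_reads, "min_reads", lower = 1)
  stopifnot_scalar_num(min_sample_fraction, "min_sample_fraction",
                       lower = 0, upper = 1, lower_open = TRUE)
  stopifnot_scalar_num(mean_reads_per_sample, "mean_reads_per_sample",
                       lower = 0, lower_open = TRUE)
  stopifnot_scalar_num(mapping_fraction, "mapping_fraction",
                       lower = 0, upper = 1, lower_open = TRUE)
  stopifnot_scalar_num(background_median_reads, "background_median_reads",
                       lower = 0)
  structure(
    list(
      rpm_cutoff = rpm_cutoff,
      min_reads = as.integer(min_reads),
      min_sample_fraction = min_sample_fraction,
      mean_reads_per_sample = mean_reads_per_sample,
      mapping_fraction = mapping_fraction,
      background_median_reads = background_median_reads
    ),
    class = "xenomir_screen_config"
  )
}

#' Sequence-match configuration
#'
#' Thresholds for classifying a candidate sequence against host references.
#' A "partial" match is a perfect common stretch of at least
#' `partial_min_stretch` nucleotides; a "near" match is a full-length
#' alignment with at most `near_max_mismatches` substitutions.
#'
#' @param partial_min_stretch Minimum length (nt) of a perfect shared
#'   stretch for a `PARTIAL` call.
#' @param near_max_mismatches Maximum substitutions in a full-length window
#'   for a `NEAR` call.
#' @param search_both_strands Also search the reverse complement of the
#'   candidate (antisense matches)?
#'
#' @return A list of class `xenomir_match_config`.
#' @export
match_config <- function(partial_min_stretch = 15L,
                         near_max_mismatches = 1L,
                         search_both_strands = TRUE) {
  stopifnot_scalar_num(partial_min_stretch, "partial_min_stretch", lower = 1)
  stopifnot_scalar_num(near_max_mismatches, "near_max_mismatches", lower = 0)
  if (!is.logical(search_both_strands) || length(search_both_strands) != 1L ||
      is.na(search_both_strands)) {
    abort("`search_both_strands` must be TRUE or FALSE.")
  }
  structure(
    list(
      partial_min_stretch = as.integer(partial_min_stretch),
      near_max_mismatches = as.integer(near_max_mismatches),
      search_both_strands = search_both_strands
    ),
    class = "xenomir_match_config"
  )
}

#' Stringent read-filter configuration
#'
#' Parameters of the host-subtraction filter: reads matching any host (or
#' extra screening) reference within `host_max_mismatches` substitutions are
#' removed before any read is assigned to a foreign reference; foreign
#' assignment always requires a perfect (0-mismatch) match.
#'
#' @param host_max_mismatches Mismatch budget for host subtraction
#'   (ungapped, full read length). The recommendation is "one or two"; the
#'   default is the permissive end, 2.
#' @param min_read_length,max_read_length Accepted read-length range (nt).
#'   Reads shorter than `min_read_length` are rejected at load as too
#'   promiscuous for perfect matching.
#'
#' @return A list of class `xenomir_filter_config`.
#' @export
filter_config <- function(host_max_mismatches = 2L,
                          min_read_length = 15L,
                          max_read_length = 35L) {
  stopifnot_scalar_num(host_max_mismatches, "host_max_mismatches", lower = 0)
  stopifnot_scalar_num(min_read_length, "min_read_length", lower = 1)
  stopifnot_scalar_num(max_read_length, "max_read_length",
                       lower = min_read_length)
  structure(
    list(
      host_max_mismatches = as.integer(host_max_mismatches),
      min_read_length = as.integer(min_read_length),
      max_read_length = as.integer(max_read_length)
    ),
    class = "xenomir_filter_config"
  )
}

#' Synthetic-study configuration
#'
#' Controls the synthetic-data generator. The defaults emulate the study
#' design the screening functions were built for: a large plasma cohort of
#' 192 libraries each sequenced twice (two of which lack a reliable second
#' run and are later excluded, leaving 190), sporadic Poisson background
#' counts for most candidates, and one consistently abundant host-derived
#' candidate whose mean count (1100 mapped reads) mirrors the single
#' above-background candidate of the reanalysed data.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param study Study label written into the sample metadata.
#' @param n_libraries Number of libraries.
#' @param runs_per_library Sequencing runs per library (counts are split
#'   binomially across runs).
#' @param n_incomplete_libraries Libraries with only a single successful
#'   run; [merge_replicate_runs()] drops them by default.
#' @param sample_type Sample type for every library, or a vector (recycled)
#'   of types from `plasma`, `cell`, `other`.
#' @param n_candidates Number of candidate miRNAs.
#' @param background_rate Poisson mean of sporadic background counts per
#'   candidate and library (low: most samples 0, a minority 1-3 reads).
#' @param n_host_derived Number of candidates given high consistent counts.
#' @param host_abundance_mean Poisson mean for host-derived candidates.
#' @param batch_multiplier Per-study multiplier on `background_rate`
#'   (a crude batch effect).
#' @param mean_total_reads,sd_total_reads Normal parameters for per-run
#'   total sequenced reads written to the metadata.
#' @param candidate_length_range Length range (nt) of simulated candidate
#'   sequences.
#' @param match_levels Planted host-match level per candidate, recycled,
#'   from `exact`, `partial15`, `near1`, `none`. The default `NULL` plants
#'   `exact` copies for host-derived candidates and nothing for background
#'   candidates.
#' @param n_host_refs Number of host reference sequences to distribute
#'   planted regions over.
#' @param flank_length_range Length range of random flanks between planted
#'   regions.
#' @param n_reads Number of simulated reads.
#' @param fraction_host_reads,fraction_foreign_reads Fractions of reads of
#'   host and foreign origin; the remainder is random noise.
#' @param read_length_range Simulated read-length range (nt).
#' @param host_read_max_mismatches Maximum substitutions injected into
#'   host-origin reads (kept within the subtraction budget).
#'
#' @return A list of class `xenomir_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       study = "plasma_cohort",
                       n_libraries = 192L,
                       runs_per_library = 2L,
                       n_incomplete_libraries = 2L,
                       sample_type = "plasma",
                       n_candidates = 20L,
                       background_rate = 0.2,
                       n_host_derived = 1L,
                       host_abundance_mean = 1100,
                       batch_multiplier = 1,
                       mean_total_reads = 6.25e6,
                       sd_total_reads = 1e6,
                       candidate_length_range = c(19L, 25L),
                       match_levels = NULL,
                       n_host_refs = 3L,
                       flank_length_range = c(60L, 120L),
                       n_reads = 1000L,
                       fraction_host_reads = 0.6,
                       fraction_foreign_reads = 0.3,
                       read_length_range = c(15L, 30L),
                       host_read_max_mismatches = 2L) {
  stopifnot_scalar_num(seed, "seed")
  stopifnot_scalar_num(n_libraries, "n_libraries", lower = 1)
  stopifnot_scalar_num(runs_per_library, "runs_per_library", lower = 1)
  stopifnot_scalar_num(n_incomplete_libraries, "n_incomplete_libraries",
                       lower = 0, upper = n_libraries)
  stopifnot_scalar_num(n_candidates, "n_candidates", lower = 1)
  stopifnot_scalar_num(background_rate, "background_rate", lower = 0)
  stopifnot_scalar_num(n_host_derived, "n_host_derived",
                       lower = 0, upper = n_candidates)
  stopifnot_scalar_num(host_abundance_mean, "host_abundance_mean", lower = 0)
  stopifnot_scalar_num(batch_multiplier, "batch_multiplier", lower = 0)
  stopifnot_scalar_num(n_reads, "n_reads", lower = 0)
  bad_type <- setdiff(sample_type, sample_types())
  if (length(bad_type)) {
    abort(paste0("Unknown sample_type: ", paste(bad_type, collapse = ", ")))
  }
  if (fraction_host_reads < 0 || fraction_foreign_reads < 0 ||
      fraction_host_reads + fraction_foreign_reads > 1) {
    abort("Read-origin fractions must be >= 0 and sum to at most 1.")
  }
  if (!is.null(match_levels)) {
    bad <- setdiff(match_levels, match_levels_set())
    if (length(bad)) {
      abort(paste0("Unknown match level: ", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      seed = as.integer(seed),
      study = study,
      n_libraries = as.integer(n_libraries),
      runs_per_library = as.integer(runs_per_library),
      n_incomplete_libraries = as.integer(n_incomplete_libraries),
      sample_type = sample_type,
      n_candidates = as.integer(n_candidates),
      background_rate = background_rate,
      n_host_derived = as.integer(n_host_derived),
      host_abundance_mean = host_abundance_mean,
      batch_multiplier = batch_multiplier,
      mean_total_reads = mean_total_reads,
      sd_total_reads = sd_total_reads,
      candidate_length_range = as.integer(candidate_length_range),
      match_levels = match_levels,
      n_host_refs = as.integer(n_host_refs),
      flank_length_range = as.integer(flank_length_range),
      n_reads = as.integer(n_reads),
      fraction_host_reads = fraction_host_reads,
      fraction_foreign_reads = fraction_foreign_reads,
      read_length_range = as.integer(read_length_range),
      host_read_max_mismatches = as.integer(host_read_max_mismatches)
    ),
    class = "xenomir_sim_config"
  )
}

#' Read a run configuration file
#'
#' Reads a YAML configuration with optional sections `screen`, `match`,
#' `filter` and `sim`, whose keys mirror the arguments of [screen_config()],
#' [match_config()], [filter_config()] and [sim_config()] exactly. Unknown
#' sections or keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A named list with elements `screen`, `match`, `filter`, `sim`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("Configuration file must contain a YAML mapping.")
  known <- list(
    screen = screen_config,
    match = match_config,
    filter = filter_config,
    sim = sim_config
  )
  bad <- setdiff(names(raw), names(known))
  if (length(bad)) {
    abort(paste0("Unknown configuration section(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- lapply(names(known), function(section) {
    ctor <- known[[section]]
    args <- raw[[section]] %||% list()
    unknown <- setdiff(names(args), names(formals(ctor)))
    if (length(unknown)) {
      abort(paste0("Unknown key(s) in section '", section, "': ",
                   paste(unknown, collapse = ", ")))
    }
    do.call(ctor, args)
  })
  stats::setNames(out, names(known))
}

sample_types <- function() c("plasma", "cell", "other")

match_levels_set <- function() c("exact", "partial15", "near1", "none")

# scalar numeric validation shared by the config constructors
stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 lower_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single non-missing number."))
  }
  ok_lower <- if (lower_open) x > lower else x >= lower
  if (!ok_lower || x > upper) {
    abort(paste0("`", name, "` is out of range."))
  }
  invisible(x)
}
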