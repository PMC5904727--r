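#' Screen a count table for candidate xenomiRs
#'
#' Umbrella over the count-screening steps: per-candidate summaries
#' ([summarize_candidates()]), the permissive inclusion screen
#' ([inclusion_screen()]) and the median background screen
#' ([background_screen()]), returning one object that [tidy()],
#' [glance()] and [autoplot()] understand.
#'
#' @param counts Long count table (one column of counts per sample; merge
#'   replicate runs first with [merge_replicate_runs()] if needed).
#' @param cfg A [screen_config()].
#' @param annotated Candidate ids with a discoverable mature sequence;
#'   `NULL` treats all as annotated.
#' @param meta Optional sample metadata (enables the average-rpm column).
#' @return An object of class `xenomir_screen`.
#' @export
#' @examples
#' sim <- simulate_count_study(sim_config(seed = 7, n_libraries = 20,
#'                                        n_candidates = 5))
#' merged <- merge_replicate_runs(sim$counts, sim$meta)
#' scr <- screen_candidates(merged$counts, meta = merged$meta)
#' glance(scr)
screen_candidates <- function(counts, cfg = screen_config(),
                              annotated = NULL, meta = NULL) {
  counts <- validate_counts(counts)
  if (!nrow(counts)) abort("Count table is empty.")
  n_samples <- n_distinct(counts$sample_id)
  summaries <- summarize_candidates(counts, cfg = cfg, meta = meta)
  included <- inclusion_from_summaries(summaries, n_samples, cfg = cfg,
                                       annotated = annotated)
  above <- background_screen(summaries, cfg = cfg)
  summaries$included <- summaries$candidate_id %in% included$candidate_id
  summaries$above_background <-
    summaries$candidate_id %in% above$candidate_id
  structure(
    list(summaries = summaries, cfg = cfg, n_samples = n_samples,
         min_samples_required = ceiling(cfg$min_sample_fraction * n_samples)),
    class = "xenomir_screen"
  )
}

#' @export
print.xenomir_screen <- function(x, ...) {
  cat("<xenomir_screen>\n")
  cat(sprintf("  %d candidates x %d samples\n",
              nrow(x$summaries), x$n_samples))
  cat(sprintf(
    "  inclusion: >= %d reads in >= %d samples -> %d candidate(s)\n",
    x$cfg$min_reads, x$min_samples_required, sum(x$summaries$included)))
  cat(sprintf("  above median-%s background: %d candidate(s)\n",
              format(x$cfg$background_median_reads),
              sum(x$summaries$above_background)))
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `xenomir_screen` object.
#' @param ... Unused.
#' @return The per-candidate summary tibble with `included` and
#'   `above_background` flags.
#' @method tidy xenomir_screen
#' @export
tidy.xenomir_screen <- function(x, ...) {
  x$summaries
}

#' One-row overview of a screen result
#'
#' @param x A `xenomir_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with candidate, sample and screen counts.
#' @method glance xenomir_screen
#' @export
glance.xenomir_screen <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$summaries),
    n_samples = x$n_samples,
    n_detected = sum(x$summaries$max_counts > 0),
    n_included = sum(x$summaries$included),
    n_above_background = sum(x$summaries$above_background)
  )
}

#' Plot a screen result
#'
#' Prevalence (samples at the minimum read count) against the estimated
#' median rpm; the horizontal line is the rpm cutoff, the vertical line
#' the inclusion sample threshold.
#'
#' @param object A `xenomir_screen` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xenomir_screen
#' @export
autoplot.xenomir_screen <- function(object, ...) {
  dat <- object$summaries
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_samples_min_reads,
                                    y = .data$est_median_rpm,
                                    colour = .data$above_background)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$cfg$rpm_cutoff,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$min_samples_required,
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = "above background") +
    ggplot2::labs(x = sprintf("samples with >= %d reads",
                              object$cfg$min_reads),
                  y = "estimated median rpm",
                  title = "xenomiR count screen") +
    ggplot2::theme_minimal()
}
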