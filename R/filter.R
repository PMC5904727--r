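#' Validate a read set
#'
#' A read set is a tibble with columns `read_id` and `seq`; an optional
#' `origin` column carries synthetic ground-truth labels.
#'
#' @param reads Data frame with `read_id`, `seq`.
#' @param cfg A [filter_config()]; read lengths outside
#'   `[min_read_length, max_read_length]` are rejected (short reads are
#'   too promiscuous for perfect matching).
#' @return The validated tibble (sequences normalized).
#' @export
validate_reads <- function(reads, cfg = filter_config()) {
  reads <- as_tibble(reads)
  need <- c("read_id", "seq")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols)) {
    abort(paste0("Read set lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(reads$read_id)) abort("Duplicated read_id in read set.")
  if (nrow(reads)) {
    reads$seq <- normalize_seq(reads$seq)
    len <- nchar(reads$seq)
    bad <- len < cfg$min_read_length | len > cfg$max_read_length
    if (any(bad)) {
      abort(sprintf(
        "%d read(s) outside the accepted length range [%d, %d] (e.g. %s).",
        sum(bad), cfg$min_read_length, cfg$max_read_length,
        reads$read_id[which(bad)[1L]]))
    }
  }
  reads
}

# minimum Hamming distance of `seq` over all windows of all references
# (both strands); returns best hit descriptors
best_reference_hit <- function(seq, refs) {
  best <- list(mm = Inf, reference_id = NA_character_,
               ref_start = NA_integer_, strand = NA_character_)
  probes <- c(`+` = seq, `-` = revcomp(seq))
  for (r in seq_len(nrow(refs))) {
    ref_int <- seq_to_int(refs$seq[r])
    if (nchar(seq) > length(ref_int)) next
    for (strand in c("+", "-")) {
      mm <- hamming_profile(ref_int, seq_to_int(probes[[strand]]))
      k <- which.min(mm)
      if (mm[k] < best$mm) {
        best <- list(mm = mm[k], reference_id = refs$id[r],
                     ref_start = k - 1L, strand = strand)
        if (best$mm == 0L && strand == "+") break
      }
    }
    if (best$mm == 0L) break
  }
  best
}

#' Subtract host-matching reads
#'
#' The first step of the stringent xenomiR filter: any read whose best
#' ungapped full-length alignment against any host (or extra screening)
#' reference, on either strand, has at most `cfg$host_max_mismatches`
#' substitutions is removed. Only the retained reads may later be assigned
#' to foreign references, so no read can be both host-removed and
#' foreign-assigned.
#'
#' @param reads Read set (see [validate_reads()]).
#' @param host_refs Host references: named character vector or `id`/`seq`
#'   data frame.
#' @param cfg A [filter_config()].
#' @param extra_refs Optional additional subtraction references (e.g.
#'   other mammals, common microbial contaminants), screened with the same
#'   budget.
#' @return A list with `retained` and `removed` read tibbles; `removed`
#'   gains columns `host_reference`, `host_mismatches`, `host_start`,
#'   `host_strand` describing the best host hit. The two sets partition
#'   the input.
#' @export
host_subtract <- function(reads, host_refs, cfg = filter_config(),
                          extra_refs = NULL) {
  reads <- validate_reads(reads, cfg)
  refs <- as_reference_tbl(host_refs)
  if (!is.null(extra_refs)) {
    refs <- bind_rows(refs, as_reference_tbl(extra_refs))
  }
  if (!nrow(refs)) abort("At least one host reference is required.")
  refs$seq <- normalize_seq(refs$seq)
  if (!nrow(reads)) {
    removed <- mutate(reads, host_reference = character(0L),
                      host_mismatches = integer(0L),
                      host_start = integer(0L),
                      host_strand = character(0L))
    return(list(retained = reads, removed = removed))
  }
  # deduplicate identical read sequences before scanning
  uniq <- unique(reads$seq)
  hits <- lapply(uniq, best_reference_hit, refs = refs)
  names(hits) <- uniq
  hit_of <- hits[reads$seq]
  mm <- vapply(hit_of, function(h) {
    if (is.finite(h$mm)) as.integer(h$mm) else NA_integer_
  }, integer(1L))
  is_removed <- !is.na(mm) & mm <= cfg$host_max_mismatches
  removed <- reads[is_removed, , drop = FALSE]
  removed$host_reference <- vapply(hit_of[is_removed], `[[`,
                                   character(1L), "reference_id")
  removed$host_mismatches <- unname(mm[is_removed])
  removed$host_start <- vapply(hit_of[is_removed], function(h) {
    as.integer(h$ref_start)
  }, integer(1L))
  removed$host_strand <- vapply(hit_of[is_removed], `[[`,
                                character(1L), "strand")
  list(retained = reads[!is_removed, , drop = FALSE], removed = removed)
}

#' Assign retained reads to foreign references by perfect match
#'
#' The second step of the stringent filter: each retained read is assigned
#' to every foreign reference that contains it with zero mismatches (both
#' strands). Reads hitting several references are reported `ambiguous`
#' (one row per reference, never resolved); reads with no perfect hit are
#' `unassigned`.
#'
#' @param retained Retained read set from [host_subtract()].
#' @param foreign_refs Foreign references: named character vector or
#'   `id`/`seq` data frame.
#' @param cfg A [filter_config()].
#' @return A tibble with `read_id`, `reference_id` (`NA` when unassigned)
#'   and `status` in `unique` / `ambiguous` / `unassigned`.
#' @export
foreign_assign <- function(retained, foreign_refs, cfg = filter_config()) {
  retained <- validate_reads(retained, cfg)
  refs <- as_reference_tbl(foreign_refs)
  refs$seq <- normalize_seq(refs$seq)
  if (!nrow(retained)) {
    return(tibble(read_id = character(0L), reference_id = character(0L),
                  status = character(0L)))
  }
  refs_rc <- revcomp(refs$seq)
  assign_one <- function(seq) {
    hit <- vapply(seq_len(nrow(refs)), function(r) {
      grepl(seq, refs$seq[r], fixed = TRUE) ||
        grepl(seq, refs_rc[r], fixed = TRUE)
    }, logical(1L))
    refs$id[hit]
  }
  uniq <- unique(retained$seq)
  hit_map <- lapply(uniq, assign_one)
  names(hit_map) <- uniq
  purrr::map2(retained$read_id, retained$seq, function(id, seq) {
    hits <- hit_map[[seq]]
    if (!length(hits)) {
      tibble(read_id = id, reference_id = NA_character_,
             status = "unassigned")
    } else {
      tibble(read_id = id, reference_id = hits,
             status = if (length(hits) > 1L) "ambiguous" else "unique")
    }
  }) |>
    bind_rows()
}

#' Summarize a stringent-filter run
#'
#' Counts of input, host-removed, uniquely foreign-assigned, ambiguous and
#' unassigned reads. The categories partition the input:
#' `host_removed + foreign_assigned + ambiguous + unassigned = input`.
#'
#' @param removed Removed read set from [host_subtract()].
#' @param assignments Assignment tibble from [foreign_assign()].
#' @return A tibble of class `xenomir_filter_summary` with `category` and
#'   `n`.
#' @export
filter_summary <- function(removed, assignments) {
  removed <- as_tibble(removed)
  assignments <- as_tibble(assignments)
  per_read <- distinct(assignments, .data$read_id, .data$status)
  n_removed <- nrow(removed)
  n_unique <- sum(per_read$status == "unique")
  n_ambiguous <- sum(per_read$status == "ambiguous")
  n_unassigned <- sum(per_read$status == "unassigned")
  out <- tibble(
    category = c("input", "host_removed", "foreign_assigned", "ambiguous",
                 "unassigned"),
    n = c(n_removed + n_unique + n_ambiguous + n_unassigned,
          n_removed, n_unique, n_ambiguous, n_unassigned)
  )
  class(out) <- c("xenomir_filter_summary", class(out))
  out
}

#' Run the full stringent filter
#'
#' Host subtraction ([host_subtract()]) followed by perfect-match foreign
#' assignment ([foreign_assign()]) and a summary.
#'
#' @inheritParams host_subtract
#' @param foreign_refs Foreign references for the assignment step.
#' @return A list with `retained`, `removed`, `assignments` and `summary`.
#' @export
filter_reads <- function(reads, host_refs, foreign_refs,
                         cfg = filter_config(), extra_refs = NULL) {
  sub <- host_subtract(reads, host_refs, cfg = cfg, extra_refs = extra_refs)
  assignments <- foreign_assign(sub$retained, foreign_refs, cfg = cfg)
  list(
    retained = sub$retained,
    removed = sub$removed,
    assignments = assignments,
    summary = filter_summary(sub$removed, assignments)
  )
}

#' Plot a stringent-filter summary
#'
#' @param object A `xenomir_filter_summary` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xenomir_filter_summary
#' @export
autoplot.xenomir_filter_summary <- function(object, ...) {
  dat <- filter(as_tibble(object), .data$category != "input")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "reads",
                  title = "Stringent host-subtraction filter") +
    ggplot2::theme_minimal()
}
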