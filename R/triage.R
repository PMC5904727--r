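#' Allowed annotation biotypes and verdict labels
#'
#' `plant_biotypes()` lists the closed set of annotation biotypes a
#' candidate can carry in its claimed (plant) species; `verdict_labels()`
#' lists the closed set of triage verdicts.
#'
#' @return Character vector.
#' @export
plant_biotypes <- function() {
  c("MIRNA", "RRNA_FRAGMENT", "TRNA_FRAGMENT", "MITOCHONDRIAL",
    "MICROSATELLITE", "MULTI_TRANSCRIPT", "UNMAPPED_IN_CLAIMED_SPECIES",
    "UNKNOWN")
}

#' @rdname plant_biotypes
#' @export
verdict_labels <- function() {
  c("HOST_SEQUENCE", "LIKELY_NONMIRNA_FRAGMENT", "DATABASE_CONTAMINANT",
    "BELOW_BACKGROUND", "PLAUSIBLE_XENOMIR", "UNRESOLVED")
}

#' Validate an annotation table
#'
#' @param annotations Data frame with columns `candidate_id`, `sequence`,
#'   `in_current_mirbase` (logical), `plant_biotype` (see
#'   [plant_biotypes()]) and `claimed_species`.
#' @return The validated tibble.
#' @export
validate_annotations <- function(annotations) {
  annotations <- as_tibble(annotations)
  need <- c("candidate_id", "sequence", "in_current_mirbase",
            "plant_biotype", "claimed_species")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols)) {
    abort(paste0("Annotation table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(annotations$candidate_id)) {
    abort("Duplicated candidate_id in annotation table.")
  }
  bad <- setdiff(unique(annotations$plant_biotype), plant_biotypes())
  if (length(bad)) {
    abort(paste0("Unknown plant_biotype value(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.logical(annotations$in_current_mirbase)) {
    abort("`in_current_mirbase` must be logical.")
  }
  annotations
}

triage_one <- function(median_counts, in_mirbase, biotype, host_category,
                       cfg) {
  fragment_biotypes <- c("RRNA_FRAGMENT", "TRNA_FRAGMENT", "MITOCHONDRIAL",
                         "MICROSATELLITE")
  above <- !is.na(median_counts) &&
    median_counts > cfg$background_median_reads
  evidence <- c(
    paste0("host_match=", host_category),
    paste0("plant_biotype=", biotype),
    paste0("in_current_mirbase=", in_mirbase),
    if (is.na(median_counts)) "median_counts=unavailable"
    else sprintf("median_counts=%s (%s background cutoff %s)",
                 format(median_counts), if (above) "above" else "at/below",
                 format(cfg$background_median_reads))
  )
  label <-
    if (host_category == "EXACT_FULL" &&
        biotype == "UNMAPPED_IN_CLAIMED_SPECIES") {
      evidence <- c(evidence,
                    "rule=exact host copy of a sequence unmapped in its claimed species")
      "DATABASE_CONTAMINANT"
    } else if (host_category %in% c("EXACT_FULL", "NEAR")) {
      evidence <- c(evidence, "rule=full-length host match (exact or near)")
      "HOST_SEQUENCE"
    } else if (biotype %in% fragment_biotypes) {
      evidence <- c(evidence, "rule=non-miRNA fragment biotype")
      "LIKELY_NONMIRNA_FRAGMENT"
    } else if (!is.na(median_counts) &&
               median_counts <= cfg$background_median_reads) {
      evidence <- c(evidence, "rule=median count at or below background")
      "BELOW_BACKGROUND"
    } else if (isTRUE(in_mirbase) && host_category == "NONE" && above) {
      evidence <- c(evidence,
                    "rule=annotated miRNA, above background, no host match")
      "PLAUSIBLE_XENOMIR"
    } else {
      evidence <- c(evidence, "rule=no decisive evidence")
      "UNRESOLVED"
    }
  if (host_category == "PARTIAL") {
    evidence <- c(evidence,
                  "note=partial host match is suggestive, not conclusive")
  }
  list(label = label, evidence = evidence)
}

#' Triage candidates into artifact / xenomiR verdicts
#'
#' Combines count-screen summaries, annotation status and host-match
#' category into one verdict per candidate through a fixed decision
#' cascade (host evidence before biotype before abundance):
#'
#' 1. host `EXACT_FULL` and biotype `UNMAPPED_IN_CLAIMED_SPECIES` ->
#'    `DATABASE_CONTAMINANT` (a host sequence contaminating the foreign
#'    database);
#' 2. host `EXACT_FULL` or `NEAR` -> `HOST_SEQUENCE`;
#' 3. biotype in rRNA / tRNA / mitochondrial / microsatellite fragments ->
#'    `LIKELY_NONMIRNA_FRAGMENT`;
#' 4. median count at or below the background threshold ->
#'    `BELOW_BACKGROUND`;
#' 5. annotated in current miRBase, no host match, above background ->
#'    `PLAUSIBLE_XENOMIR`; otherwise `UNRESOLVED`.
#'
#' `PARTIAL` host matches never force `HOST_SEQUENCE`; they are recorded
#' in the evidence only. Candidates missing from `summaries` are triaged
#' without an abundance rule (rule 4 and the above-background requirement
#' of rule 5 cannot fire).
#'
#' @param summaries Tibble from [summarize_candidates()] (may omit
#'   candidates; may be `NULL`).
#' @param annotations Annotation table (see [validate_annotations()]); its
#'   candidates drive the output.
#' @param matches Tibble of host-match reports from
#'   [classify_host_matches()]; must cover every annotated candidate.
#' @param cfg A [screen_config()] (for the background threshold).
#' @return A tibble of class `xenomir_triage` with `candidate_id`, `label`
#'   and an `evidence` list-column of tagged reasons.
#' @export
triage <- function(summaries, annotations, matches, cfg = screen_config()) {
  annotations <- validate_annotations(annotations)
  matches <- as_tibble(matches)
  missing_match <- setdiff(annotations$candidate_id, matches$candidate_id)
  if (length(missing_match)) {
    abort(paste0("No host-match report for candidate(s): ",
                 paste(head(missing_match, 5L), collapse = ", ")))
  }
  med <- if (is.null(summaries)) {
    tibble(candidate_id = character(0L), median_counts = numeric(0L))
  } else {
    select(as_tibble(summaries), "candidate_id", "median_counts")
  }
  if (anyDuplicated(med$candidate_id)) {
    abort("Duplicated candidate_id in summaries; supply one row per candidate.")
  }
  joined <- annotations |>
    left_join(med, by = "candidate_id") |>
    left_join(select(matches, "candidate_id", host_category = "category"),
              by = "candidate_id")
  res <- purrr::pmap(
    list(joined$median_counts, joined$in_current_mirbase,
         joined$plant_biotype, joined$host_category),
    triage_one, cfg = cfg
  )
  out <- tibble(
    candidate_id = joined$candidate_id,
    label = vapply(res, `[[`, character(1L), "label"),
    evidence = lapply(res, `[[`, "evidence")
  )
  class(out) <- c("xenomir_triage", class(out))
  out
}

#' Tabulate triage verdicts
#'
#' One row per candidate with its label and collapsed evidence string, in
#' stable input order, with per-label counts attached as a footer
#' (attribute `label_counts`; written as trailing comment lines by
#' [write_triage_report()]).
#'
#' @param verdicts Output of [triage()].
#' @return A tibble with attribute `label_counts`.
#' @export
triage_report <- function(verdicts) {
  verdicts <- as_tibble(verdicts)
  out <- tibble(
    candidate_id = verdicts$candidate_id,
    label = verdicts$label,
    evidence = vapply(verdicts$evidence, paste, character(1L),
                      collapse = "; ")
  )
  counts <- table(factor(verdicts$label, levels = verdict_labels()))
  attr(out, "label_counts") <- tibble(
    label = names(counts),
    n = as.integer(counts)
  )
  out
}

#' Write a triage report to TSV
#'
#' @param verdicts Output of [triage()].
#' @param path Output file; the per-label counts are appended as `#`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_triage_report <- function(verdicts, path) {
  report <- triage_report(verdicts)
  readr::write_tsv(report, path)
  counts <- attr(report, "label_counts")
  footer <- sprintf("# %s\t%d", counts$label, counts$n)
  con <- file(path, open = "at")
  on.exit(close(con))
  writeLines(footer, con)
  invisible(path)
}

#' Plot triage verdict counts
#'
#' @param object A `xenomir_triage` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xenomir_triage
#' @export
autoplot.xenomir_triage <- function(object, ...) {
  counts <- attr(triage_report(object), "label_counts")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "candidates",
                  title = "Triage verdicts") +
    ggplot2::theme_minimal()
}
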