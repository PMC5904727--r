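#' Packaged annotation table for the 15 recurrent plasma candidates
#'
#' The 15 putative plant miRNAs that pass the permissive inclusion screen
#' in reanalyses of two public human plasma / cell small-RNA datasets,
#' with their printed mature sequences (RNA, as published), current
#' miRBase status, annotation biotype in the claimed plant species, the
#' cohort(s) they were recurrent in, and the host-match category each
#' sequence shows against human references (`reported_host_match`,
#' with strand `-` marking the one antisense match).
#'
#' @return An annotation tibble (see [validate_annotations()]) with extra
#'   columns `cohort` and `reported_host_match`.
#' @export
candidate_annotations <- function() {
  tibble::tribble(
    ~candidate_id, ~sequence, ~in_current_mirbase, ~plant_biotype,
    ~claimed_species, ~cohort, ~reported_host_match,
    "peu-MIR2910", "UAGUUGGUGGAGCGAUUUGUC", FALSE, "RRNA_FRAGMENT",
    "Populus euphratica", "both", "EXACT_FULL",
    "peu-MIR2916", "UGGGGACUCGAAGACGAUCAUAU", TRUE, "UNKNOWN",
    "Populus euphratica", "plasma_cohort", "PARTIAL",
    "tae-MIR2005", "GGGUGUAUAGCUCAGUUGG", FALSE, "MITOCHONDRIAL",
    "Triticum aestivum", "both", "PARTIAL",
    "peu-MIR2914", "CAUGGUGGUGACGGGUGACGGAG", FALSE, "RRNA_FRAGMENT",
    "Populus euphratica", "both", "PARTIAL",
    "tae-MIR2018", "GCCCGUCUAGCUCAGUUGGU", FALSE, "MULTI_TRANSCRIPT",
    "Triticum aestivum", "both", "PARTIAL",
    "ath-MIRf10482-akr", "UCUACUCGACUAGGUGGUCGAGUGG", FALSE, "UNKNOWN",
    "Arabidopsis thaliana", "plasma_cohort", "PARTIAL",
    "ppt-MIR896", "GUCAAUUUGGCCGAGUGGUUAAGGC", FALSE, "TRNA_FRAGMENT",
    "Physcomitrella patens", "plasma_cohort", "PARTIAL",
    "ptc-MIRf12412-akr", "GCUGGGAUUACAGGCGUGAGCCACC", FALSE,
    "UNMAPPED_IN_CLAIMED_SPECIES",
    "Populus trichocarpa", "both", "EXACT_FULL",
    "peu-MIR2911", "GGCCGGGGGACGGGCUGGGA", FALSE, "RRNA_FRAGMENT",
    "Populus euphratica", "plasma_cohort", "NEAR",
    "ppt-MIR894", "CGUUUCACGUCGGGUUCACC", TRUE, "MULTI_TRANSCRIPT",
    "Physcomitrella patens", "plasma_cohort", "NONE",
    "ptc-MIRf12524-akr", "CCUGUAAUCCCAGCUACUCGGG", FALSE,
    "UNMAPPED_IN_CLAIMED_SPECIES",
    "Populus trichocarpa", "both", "EXACT_FULL",
    "ath-MIRf10045-akr", "UCUACUCGACCUGGUGGUCGAGUGGU", FALSE, "UNKNOWN",
    "Arabidopsis thaliana", "mixed_cohort", "PARTIAL",
    "ath-MIRf10046-akr", "CUCGACCUGGUGGUCGAGUGGU", FALSE, "UNKNOWN",
    "Arabidopsis thaliana", "mixed_cohort", "PARTIAL",
    "peu-MIR2915", "CCCGUCUAGCUCAGUUGGUA", FALSE, "TRNA_FRAGMENT",
    "Populus euphratica", "mixed_cohort", "PARTIAL",
    "ptc-MIRf10804-akr", "CCUGUAAUCCCAGCACUUUGG", FALSE, "MICROSATELLITE",
    "Populus trichocarpa", "mixed_cohort", "EXACT_FULL"
  )
}

#' Published per-candidate screening summaries
#'
#' Per-candidate screening statistics reported for the reanalyses of two
#' public datasets: a large plasma cohort (`plasma_cohort`, 190 merged
#' libraries out of 192 sequenced) and a mixed cohort of 17 cell and 6
#' plasma samples (`mixed_cohort`, 23 samples; its plasma-only restriction
#' is `mixed_plasma`, 6 samples). Columns mirror
#' [summarize_candidates()]: samples with at least 3 mapped reads, mean /
#' median / max mapped counts, the estimated median rpm (plasma cohort;
#' back-computed from the median at mapping fraction 0.475) and the
#' average rpm over total sequenced reads (mixed cohort).
#'
#' @return A tibble with one row per candidate and cohort.
#' @export
reference_candidate_summaries <- function() {
  tibble::tribble(
    ~cohort, ~n_samples, ~candidate_id, ~n_samples_min_reads,
    ~mean_counts, ~median_counts, ~max_counts, ~est_median_rpm, ~avg_rpm,
    "plasma_cohort", 190L, "peu-MIR2910", 190L, 1143.4, 1072.5, 2020, 180.6, NA,
    "plasma_cohort", 190L, "peu-MIR2916", 190L, 119.7, 115, 315, 19.4, NA,
    "plasma_cohort", 190L, "tae-MIR2005", 178L, 8.7, 9, 23, 1.5, NA,
    "plasma_cohort", 190L, "peu-MIR2914", 169L, 14.3, 9, 348, 1.5, NA,
    "plasma_cohort", 190L, "tae-MIR2018", 167L, 5.9, 6, 14, 1.0, NA,
    "plasma_cohort", 190L, "ath-MIRf10482-akr", 161L, 7.3, 6, 29, 1.0, NA,
    "plasma_cohort", 190L, "ppt-MIR896", 147L, 4.6, 4, 15, 0.7, NA,
    "plasma_cohort", 190L, "ptc-MIRf12412-akr", 47L, 2.7, 2, 18, 0.3, NA,
    "plasma_cohort", 190L, "peu-MIR2911", 42L, 2.6, 2, 10, 0.3, NA,
    "plasma_cohort", 190L, "ppt-MIR894", 39L, 2.3, 2, 18, 0.3, NA,
    "plasma_cohort", 190L, "ptc-MIRf12524-akr", 28L, 1.8, 1, 5, 0.2, NA,
    "mixed_cohort", 23L, "peu-MIR2910", 21L, 370, 41.5, 5369, NA, 21.3,
    "mixed_cohort", 23L, "ptc-MIRf10804-akr", 17L, 26, 26, 60, NA, 1.2,
    "mixed_cohort", 23L, "ptc-MIRf12412-akr", 17L, 63, 61, 156, NA, 2.8,
    "mixed_cohort", 23L, "tae-MIR2018", 17L, 39, 29, 163, NA, 1.7,
    "mixed_cohort", 23L, "ptc-MIRf12524-akr", 10L, 13, 10.5, 31, NA, 0.4,
    "mixed_cohort", 23L, "tae-MIR2005", 7L, 17, 11, 69, NA, 0.4,
    "mixed_cohort", 23L, "ath-MIRf10045-akr", 4L, 5, 4, 10, NA, 0.1,
    "mixed_cohort", 23L, "ath-MIRf10046-akr", 4L, 5, 4, 10, NA, 0.1,
    "mixed_cohort", 23L, "peu-MIR2914", 3L, 26, 11, 81, NA, 0.3,
    "mixed_cohort", 23L, "peu-MIR2915", 3L, 5, 4.5, 8, NA, 0.0,
    "mixed_plasma", 6L, "peu-MIR2910", 6L, 1210, 480.5, 5369, NA, 83.2,
    "mixed_plasma", 6L, "ptc-MIRf10804-akr", 0L, 0, 0, 0, NA, 0,
    "mixed_plasma", 6L, "ptc-MIRf12412-akr", 0L, 0, 0, 0, NA, 0,
    "mixed_plasma", 6L, "tae-MIR2018", 0L, 0, 0, 0, NA, 0,
    "mixed_plasma", 6L, "ptc-MIRf12524-akr", 2L, 16, 16, 31, NA, 0.4,
    "mixed_plasma", 6L, "tae-MIR2005", 0L, 0, 0, 0, NA, 0,
    "mixed_plasma", 6L, "ath-MIRf10045-akr", 0L, 0, 0, 0, NA, 0,
    "mixed_plasma", 6L, "ath-MIRf10046-akr", 0L, 0, 0, 0, NA, 0,
    "mixed_plasma", 6L, "peu-MIR2914", 3L, 33.7, 19, 81, NA, 1.2,
    "mixed_plasma", 6L, "peu-MIR2915", 0L, 0, 0, 0, NA, 0
  )
}

#' Study designs of the two reanalysed public cohorts
#'
#' Sample composition of the two public small-RNA datasets the screening
#' conditions are built around: a plasma cohort of 192 libraries (each
#' sequenced twice) and a mixed cohort of 6 plasma, 6 PBMC and 11
#' cultured-cell-line samples.
#'
#' @return A tibble with `study`, `sample_type`, `n_samples`,
#'   `runs_per_library`.
#' @export
cohort_designs <- function() {
  tibble::tribble(
    ~study, ~sample_type, ~n_samples, ~runs_per_library,
    "plasma_cohort", "plasma", 192L, 2L,
    "mixed_cohort", "plasma", 6L, 1L,
    "mixed_cohort", "cell", 17L, 1L
  )
}

#' Synthetic host references with planted candidate matches
#'
#' A deterministic, synthetic stand-in for the human reference records the
#' 15 packaged candidates match: each candidate's planted region realizes
#' its reported host-match category (`EXACT_FULL`: verbatim copy, for one
#' candidate on the antisense strand; `NEAR`: full-length copy with one
#' substitution; `PARTIAL`: a 15-nt fragment; `NONE`: nothing planted).
#' Fragments are embedded between fixed pseudo-random spacers, so the
#' construction is byte-stable across calls. These references are
#' synthetic sequences, not the GenBank records themselves.
#'
#' @return A list with `references` (`id`/`seq` tibble) and `expected`
#'   (tibble of `candidate_id` and the match category the construction
#'   plants).
#' @export
synthetic_host_references <- function() {
  ann <- candidate_annotations()
  seqs <- stats::setNames(normalize_seq(ann$sequence), ann$candidate_id)
  frag15 <- function(id, start) substr(seqs[[id]], start, start + 14L)
  withr::with_seed(104729L, {
    spacer <- function() {
      paste(sample(c("A", "C", "G", "T"), sample(40:70, 1L),
                   replace = TRUE), collapse = "")
    }
    build <- function(parts) {
      paste(c(spacer(), unlist(lapply(parts, function(p) c(p, spacer())))),
            collapse = "")
    }
    near_2911 <- substitute_base(seqs[["peu-MIR2911"]], 10L)
    references <- tibble(
      id = c("synthetic_rRNA_like", "synthetic_transcript_like",
             "synthetic_genomic_like", "synthetic_chromosomal_like"),
      seq = c(
        # 18S-rRNA-like record: exact MIR2910 plus rRNA-fragment partials
        build(list(seqs[["peu-MIR2910"]],
                   frag15("peu-MIR2916", 1L),
                   frag15("peu-MIR2914", 1L))),
        # transcript-like record: exact sense and antisense copies plus
        # tRNA-like partials
        build(list(seqs[["ptc-MIRf12412-akr"]],
                   revcomp(seqs[["ptc-MIRf10804-akr"]]),
                   frag15("tae-MIR2005", 1L),
                   frag15("tae-MIR2018", 1L))),
        # genomic-like record: exact copy, one-mismatch 20-nt stretch,
        # and further partials
        build(list(seqs[["ptc-MIRf12524-akr"]],
                   near_2911,
                   frag15("ath-MIRf10482-akr", 1L),
                   frag15("ppt-MIR896", 1L))),
        # chromosomal-like record: partials, one fragment shared by the
        # nested candidate pair
        build(list(frag15("ath-MIRf10045-akr", 8L),
                   frag15("peu-MIR2915", 1L)))
      )
    )
  })
  list(
    references = references,
    expected = tibble(
      candidate_id = ann$candidate_id,
      category = ann$reported_host_match
    )
  )
}
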