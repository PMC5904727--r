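#' Simulate a count study with ground truth
#'
#' Generates a candidate-by-run count table with the statistical structure
#' the screening assumes: most candidates draw sporadic low Poisson
#' background counts (contamination / sequencing-error-like noise, batch
#' scaled by `batch_multiplier`), while `n_host_derived` candidates draw
#' high consistent counts in every library. Each library's count is then
#' split binomially (equal run probabilities) across `runs_per_library`
#' sequencing runs; `n_incomplete_libraries` libraries get a single run
#' only, emulating libraries without a reliable replicate.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (run-level long count table), `meta`
#'   (run-level sample metadata) and `truth` (list with `candidates`:
#'   per-candidate true class, and `library_counts`: library-level counts
#'   before the run split).
#' @export
simulate_count_study <- function(cfg = sim_config()) {
  if (cfg$n_libraries < 1L || cfg$n_candidates < 1L) {
    abort("Degenerate configuration: need at least one library and candidate.")
  }
  withr::with_seed(cfg$seed, {
    cand_ids <- sprintf("cand%03d", seq_len(cfg$n_candidates))
    lib_ids <- sprintf("lib%03d", seq_len(cfg$n_libraries))
    classes <- c(rep("host_derived", cfg$n_host_derived),
                 rep("background", cfg$n_candidates - cfg$n_host_derived))
    rate <- ifelse(classes == "host_derived", cfg$host_abundance_mean,
                   cfg$background_rate * cfg$batch_multiplier)
    lib_counts <- tidyr::expand_grid(candidate_id = cand_ids,
                                     sample_id = lib_ids)
    lib_counts$count <- rpois(nrow(lib_counts),
                              rate[match(lib_counts$candidate_id, cand_ids)])

    # incomplete libraries: single run carrying the full library count
    incomplete <- if (cfg$n_incomplete_libraries > 0L) {
      lib_ids[seq(cfg$n_libraries - cfg$n_incomplete_libraries + 1L,
                  cfg$n_libraries)]
    } else {
      character(0L)
    }
    runs_of <- function(lib) {
      k <- if (lib %in% incomplete) 1L else cfg$runs_per_library
      paste0(lib, "_run", seq_len(k))
    }

    run_rows <- lapply(lib_ids, function(lib) {
      block <- lib_counts[lib_counts$sample_id == lib, ]
      runs <- runs_of(lib)
      k <- length(runs)
      split_counts <- matrix(0L, nrow = nrow(block), ncol = k)
      remaining <- block$count
      for (j in seq_len(k - 1L)) {
        drawn <- rbinom(length(remaining), remaining,
                        1 / (k - j + 1L))
        split_counts[, j] <- drawn
        remaining <- remaining - drawn
      }
      split_counts[, k] <- remaining
      tibble(
        candidate_id = rep(block$candidate_id, times = k),
        sample_id = rep(runs, each = nrow(block)),
        count = as.integer(split_counts)
      )
    })
    counts <- bind_rows(run_rows)

    meta <- bind_rows(lapply(lib_ids, function(lib) {
      runs <- runs_of(lib)
      tibble(sample_id = runs, library_id = lib)
    }))
    types <- rep_len(cfg$sample_type, cfg$n_libraries)
    meta$study <- cfg$study
    meta$sample_type <- types[match(meta$library_id, lib_ids)]
    meta$total_reads <- pmax(round(rnorm(nrow(meta), cfg$mean_total_reads,
                                         cfg$sd_total_reads)), 1e5)

    list(
      counts = counts,
      meta = meta,
      truth = list(
        candidates = tibble(candidate_id = cand_ids, true_class = classes),
        library_counts = lib_counts
      )
    )
  })
}

random_dna <- function(lens) {
  vapply(lens, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

substitute_base <- function(seq, pos) {
  base <- substr(seq, pos, pos)
  repl <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
  paste0(substr(seq, 1L, pos - 1L), repl, substr(seq, pos + 1L, nchar(seq)))
}

#' Simulate candidate, host and foreign references with planted matches
#'
#' Generates random candidate sequences and host references in which each
#' candidate has a planted region realizing its configured match level:
#' `exact` (verbatim copy), `partial15` (a shared stretch of exactly 15 nt,
#' the partial-match boundary), `near1` (full-length copy with exactly one
#' substitution) or `none` (no planted region). Foreign references contain
#' every candidate verbatim. With the default `match_levels = NULL`,
#' host-derived candidates (per [sim_config()]) are planted `exact` and
#' background candidates `none`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `candidates`, `host`, `foreign` (each an `id`/`seq`
#'   tibble) and `truth` (planted level and coordinates per candidate).
#' @export
simulate_references <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_candidates
    cand_ids <- sprintf("cand%03d", seq_len(n))
    lens <- sample(seq(cfg$candidate_length_range[1L],
                       cfg$candidate_length_range[2L]), n, replace = TRUE)
    seqs <- random_dna(lens)
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- random_dna(lens[dup])
    }
    levels <- if (is.null(cfg$match_levels)) {
      ifelse(seq_len(n) <= cfg$n_host_derived, "exact", "none")
    } else {
      rep_len(cfg$match_levels, n)
    }

    planted <- purrr::pmap(list(cand_ids, seqs, levels),
                           function(id, seq, level) {
      frag <- switch(level,
        exact = seq,
        partial15 = {
          start <- sample(nchar(seq) - 15L + 1L, 1L)
          substr(seq, start, start + 14L)
        },
        near1 = substitute_base(seq, max(2L, nchar(seq) %/% 2L)),
        none = NA_character_
      )
      tibble(candidate_id = id, level = level, fragment = frag)
    }) |>
      bind_rows()

    with_frag <- planted[!is.na(planted$fragment), , drop = FALSE]
    host_ids <- sprintf("host_ref%02d", seq_len(cfg$n_host_refs))
    assignment <- if (nrow(with_frag)) {
      rep_len(seq_len(cfg$n_host_refs), nrow(with_frag))
    } else {
      integer(0L)
    }
    flank <- function() {
      random_dna(sample(seq(cfg$flank_length_range[1L],
                            cfg$flank_length_range[2L]), 1L))
    }
    truth_rows <- list()
    host_seqs <- vapply(seq_len(cfg$n_host_refs), function(r) {
      frags <- with_frag[assignment == r, , drop = FALSE]
      parts <- flank()
      for (j in seq_len(nrow(frags))) {
        start <- sum(nchar(parts))
        truth_rows[[length(truth_rows) + 1L]] <<- tibble(
          candidate_id = frags$candidate_id[j],
          level = frags$level[j],
          host_reference = host_ids[r],
          planted_start = start,
          planted_end = start + nchar(frags$fragment[j]),
          strand = "+"
        )
        parts <- c(parts, frags$fragment[j], flank())
      }
      paste(parts, collapse = "")
    }, character(1L))

    foreign_flanked <- unlist(lapply(seqs, function(s) c(s, flank())))
    foreign <- tibble(
      id = "foreign_ref01",
      seq = paste(c(flank(), foreign_flanked), collapse = "")
    )

    truth <- bind_rows(
      bind_rows(truth_rows),
      tibble(candidate_id = planted$candidate_id[is.na(planted$fragment)],
             level = "none", host_reference = NA_character_,
             planted_start = NA_integer_, planted_end = NA_integer_,
             strand = NA_character_)
    ) |>
      arrange(.data$candidate_id)

    list(
      candidates = tibble(id = cand_ids, seq = seqs),
      host = tibble(id = host_ids, seq = host_seqs),
      foreign = foreign,
      truth = truth
    )
  })
}

#' Simulate a labeled read set
#'
#' Draws reads of three origins with ground-truth labels: host-origin
#' reads are windows of the host references with 0 to
#' `host_read_max_mismatches` substitutions injected; foreign-origin reads
#' are verbatim windows of the foreign references (rejected and redrawn if
#' they also match a host reference within the mismatch budget, so labels
#' stay consistent with the emitted sequences); noise reads are random
#' (rejected if they match host within budget or any foreign reference
#' perfectly). Each read is reverse-complemented with probability 1/2.
#'
#' @param cfg A [sim_config()].
#' @param refs References from [simulate_references()]; generated from
#'   `cfg` when omitted.
#' @return A list with `reads` (read set with ground-truth `origin`
#'   column) and `refs`.
#' @export
simulate_reads <- function(cfg = sim_config(), refs = NULL) {
  refs <- refs %||% simulate_references(cfg)
  withr::with_seed(cfg$seed + 2L, {
    n_host <- round(cfg$n_reads * cfg$fraction_host_reads)
    n_foreign <- round(cfg$n_reads * cfg$fraction_foreign_reads)
    n_noise <- cfg$n_reads - n_host - n_foreign
    len_range <- seq(cfg$read_length_range[1L], cfg$read_length_range[2L])

    host_tbl <- refs$host
    foreign_tbl <- refs$foreign

    min_host_mm <- function(seq) {
      best_reference_hit(seq, host_tbl)$mm
    }
    perfect_foreign <- function(seq) {
      any(vapply(seq_len(nrow(foreign_tbl)), function(r) {
        grepl(seq, foreign_tbl$seq[r], fixed = TRUE) ||
          grepl(seq, revcomp(foreign_tbl$seq[r]), fixed = TRUE)
      }, logical(1L)))
    }
    window_of <- function(tbl) {
      len <- sample(len_range, 1L)
      r <- sample(nrow(tbl), 1L)
      ref <- tbl$seq[r]
      if (nchar(ref) < len) len <- nchar(ref)
      start <- sample(nchar(ref) - len + 1L, 1L)
      substr(ref, start, start + len - 1L)
    }
    orient <- function(seq) if (runif(1L) < 0.5) revcomp(seq) else seq

    draw_host <- function() {
      seq <- window_of(host_tbl)
      k <- sample(0:cfg$host_read_max_mismatches, 1L)
      for (j in seq_len(k)) {
        seq <- substitute_base(seq, sample(nchar(seq), 1L))
      }
      # injected substitutions can exceed the budget only if k were larger
      # than allowed; guard against pathological double-hits on one base
      if (min_host_mm(seq) > cfg$host_read_max_mismatches) return(NULL)
      orient(seq)
    }
    draw_foreign <- function() {
      seq <- window_of(foreign_tbl)
      if (min_host_mm(seq) <= cfg$host_read_max_mismatches) return(NULL)
      if (!perfect_foreign(seq)) return(NULL)
      orient(seq)
    }
    draw_noise <- function() {
      seq <- random_dna(sample(len_range, 1L))
      if (min_host_mm(seq) <= cfg$host_read_max_mismatches) return(NULL)
      if (perfect_foreign(seq)) return(NULL)
      seq
    }
    draw_n <- function(n, draw, what) {
      out <- character(0L)
      tries <- 0L
      while (length(out) < n) {
        tries <- tries + 1L
        if (tries > 50L * max(n, 1L)) {
          abort(paste0("Could not generate ", what,
                       " reads consistent with their label; ",
                       "references overlap too strongly."))
        }
        seq <- draw()
        if (!is.null(seq)) out <- c(out, seq)
      }
      out
    }

    seqs <- c(
      if (n_host > 0L) draw_n(n_host, draw_host, "host"),
      if (n_foreign > 0L) draw_n(n_foreign, draw_foreign, "foreign"),
      if (n_noise > 0L) draw_n(n_noise, draw_noise, "noise")
    )
    origin <- c(rep("host", n_host), rep("foreign", n_foreign),
                rep("noise", n_noise))
    reads <- tibble(
      read_id = sprintf("read%05d", seq_along(seqs)),
      seq = seqs,
      origin = origin
    )
    list(reads = reads, refs = refs)
  })
}
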