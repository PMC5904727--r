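#' Normalize a nucleotide sequence
#'
#' Candidate miRNAs are printed as RNA while references are DNA records, so
#' all comparisons happen in a normalized DNA alphabet: whitespace is
#' stripped, case folded to upper, and U mapped to T. Normalization is
#' lossy by design (the original U/T form is not preserved). Ambiguity
#' codes (N, R, Y, ...) are rejected: the match categories are defined on
#' exact identity, not wildcard matching.
#'
#' @param x Character vector of raw sequence text.
#' @return Character vector over `{A,C,G,T}`; names preserved.
#' @export
#' @examples
#' normalize_seq("uagUUGGU")
normalize_seq <- function(x) {
  if (!is.character(x) || !length(x)) {
    abort("`x` must be a non-empty character vector.")
  }
  out <- toupper(gsub("[[:space:]]", "", x))
  if (any(!nzchar(out))) {
    abort("Empty sequence after whitespace stripping.")
  }
  bad <- regexpr("[^ACGTU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf("Disallowed character '%s' at position %d of sequence %s.",
                  substr(out[i], bad[i], bad[i]), bad[i],
                  if (!is.null(names(x)[i]) && !is.na(names(x)[i]))
                    names(x)[i] else i))
  }
  chartr("U", "T", out)
}

#' Reverse complement
#'
#' @param x Character vector of normalized DNA sequences.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGT", "TGCA", x), function(s) {
    rawToChar(rev(charToRaw(s)))
  }, character(1L), USE.NAMES = FALSE)
}

# integer codes for fast vectorized comparison
seq_to_int <- function(s) utf8ToInt(s)

# mismatch count of `cand` against every same-length window of `ref`
hamming_profile <- function(ref_int, cand_int) {
  nw <- length(ref_int) - length(cand_int) + 1L
  if (nw < 1L) return(integer(0L))
  mm <- integer(nw)
  for (i in seq_along(cand_int)) {
    mm <- mm + (ref_int[i:(i + nw - 1L)] != cand_int[i])
  }
  mm
}

match_report_row <- function(candidate_id, reference_id, category,
                             ref_start = NA_integer_, ref_end = NA_integer_,
                             strand = NA_character_,
                             mismatches = NA_integer_,
                             matched_length = NA_integer_) {
  tibble(
    candidate_id = candidate_id,
    reference_id = reference_id,
    category = category,
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    strand = strand,
    mismatches = as.integer(mismatches),
    matched_length = as.integer(matched_length)
  )
}

#' Full-length exact occurrences of a candidate in a reference
#'
#' Finds every full-length, zero-mismatch occurrence of the candidate on
#' the reference forward strand and, if `cfg$search_both_strands`, of its
#' reverse complement (reported with strand `-` but always in forward-
#' strand coordinates). Coordinates are 0-based half-open. Hits are ordered
#' left to right, `+` strand before `-`.
#'
#' @param candidate,reference Sequence strings (normalized internally).
#' @param cfg A [match_config()].
#' @param candidate_id,reference_id Identifiers copied into the report.
#' @return A tibble of `EXACT_FULL` match reports (possibly empty).
#' @export
#' @examples
#' exact_search("ACGT", "TTACGTTT")
exact_search <- function(candidate, reference, cfg = match_config(),
                         candidate_id = "candidate",
                         reference_id = "reference") {
  candidate <- normalize_seq(candidate)
  reference <- normalize_seq(reference)
  m <- nchar(candidate)
  if (m > nchar(reference)) {
    abort("Candidate is longer than the reference.")
  }
  ref_int <- seq_to_int(reference)
  hits <- list()
  strands <- if (cfg$search_both_strands) c("+", "-") else "+"
  for (strand in strands) {
    probe <- if (strand == "+") candidate else revcomp(candidate)
    # a reverse-complement palindrome hits identically on both strands;
    # report the forward hit only
    if (strand == "-" && probe == candidate) next
    starts <- which(hamming_profile(ref_int, seq_to_int(probe)) == 0L) - 1L
    if (length(starts)) {
      hits[[strand]] <- match_report_row(
        candidate_id, reference_id, "EXACT_FULL",
        ref_start = starts, ref_end = starts + m,
        strand = strand, mismatches = 0L, matched_length = m
      )
    }
  }
  if (!length(hits)) {
    return(match_report_row(candidate_id, reference_id, "NONE")[0L, ])
  }
  bind_rows(hits)
}

# longest common substring of cand vs ref on one strand; returns
# list(len, ref_start) with 0-based ref_start (smallest on ties)
lcs_one_strand <- function(cand_int, ref_int) {
  n <- length(ref_int)
  prev <- integer(n)
  best_len <- 0L
  best_start <- NA_integer_
  for (i in seq_along(cand_int)) {
    eq <- ref_int == cand_int[i]
    cur <- integer(n)
    if (any(eq)) cur[eq] <- c(0L, prev[-n])[eq] + 1L
    mx <- max(cur)
    if (mx > best_len) {
      best_len <- mx
      best_start <- min(which(cur == mx)) - mx
    } else if (mx == best_len && mx > 0L) {
      best_start <- min(best_start, min(which(cur == mx)) - mx)
    }
    prev <- cur
  }
  list(len = best_len, ref_start = best_start)
}

#' Longest perfect shared stretch between candidate and reference
#'
#' Finds the longest common substring between the candidate and the
#' reference (both strands if configured). The result is `PARTIAL` when
#' the stretch reaches `cfg$partial_min_stretch` (default 15 nt with 100%
#' identity), otherwise `NONE`. Multiple disjoint stretches are never
#' summed. Ties go to the smallest `ref_start`, then the `+` strand.
#'
#' @inheritParams exact_search
#' @return A one-row match report tibble.
#' @export
longest_perfect_stretch <- function(candidate, reference,
                                    cfg = match_config(),
                                    candidate_id = "candidate",
                                    reference_id = "reference") {
  candidate <- normalize_seq(candidate)
  reference <- normalize_seq(reference)
  ref_int <- seq_to_int(reference)
  plus <- lcs_one_strand(seq_to_int(candidate), ref_int)
  best <- c(plus, strand = "+")
  if (cfg$search_both_strands) {
    minus <- lcs_one_strand(seq_to_int(revcomp(candidate)), ref_int)
    if (minus$len > best$len ||
        (minus$len == best$len && minus$len > 0L &&
         minus$ref_start < best$ref_start)) {
      best <- c(minus, strand = "-")
    }
  }
  if (best$len >= cfg$partial_min_stretch) {
    match_report_row(candidate_id, reference_id, "PARTIAL",
                     ref_start = best$ref_start,
                     ref_end = best$ref_start + best$len,
                     strand = best$strand, mismatches = 0L,
                     matched_length = best$len)
  } else {
    match_report_row(candidate_id, reference_id, "NONE",
                     matched_length = best$len, mismatches = NA_integer_)
  }
}

#' Best full-length windowed match of a candidate in a reference
#'
#' Slides the full-length candidate over every same-length window of the
#' reference (both strands if configured), counting substitutions
#' (Hamming distance; ungapped). Returns the minimum-mismatch window:
#' `EXACT_FULL` at 0 mismatches, `NEAR` at 1 to
#' `cfg$near_max_mismatches`, otherwise `NONE` (no coordinates, but the
#' observed minimum is reported). Ties go to the smallest `ref_start`,
#' then the `+` strand.
#'
#' @inheritParams exact_search
#' @return A one-row match report tibble.
#' @export
best_windowed_match <- function(candidate, reference, cfg = match_config(),
                                candidate_id = "candidate",
                                reference_id = "reference") {
  candidate <- normalize_seq(candidate)
  reference <- normalize_seq(reference)
  m <- nchar(candidate)
  if (m > nchar(reference)) {
    abort("Candidate is longer than the reference.")
  }
  ref_int <- seq_to_int(reference)
  best <- NULL
  strands <- if (cfg$search_both_strands) c("+", "-") else "+"
  for (strand in strands) {
    probe <- if (strand == "+") candidate else revcomp(candidate)
    mm <- hamming_profile(ref_int, seq_to_int(probe))
    k <- which.min(mm)
    cand_best <- list(mm = mm[k], ref_start = k - 1L, strand = strand)
    if (is.null(best) || cand_best$mm < best$mm ||
        (cand_best$mm == best$mm && cand_best$ref_start < best$ref_start)) {
      best <- cand_best
    }
  }
  category <- if (best$mm == 0L) {
    "EXACT_FULL"
  } else if (best$mm <= cfg$near_max_mismatches) {
    "NEAR"
  } else {
    "NONE"
  }
  if (category == "NONE") {
    match_report_row(candidate_id, reference_id, "NONE",
                     mismatches = best$mm)
  } else {
    match_report_row(candidate_id, reference_id, category,
                     ref_start = best$ref_start, ref_end = best$ref_start + m,
                     strand = best$strand, mismatches = best$mm,
                     matched_length = m)
  }
}

#' Containment of one candidate within another
#'
#' Tests whether `inner` occurs as a contiguous substring of `outer`
#' (forward strand only) and reports the 0-based offset of the first
#' occurrence.
#'
#' @param outer,inner Sequence strings (normalized internally).
#' @return A list with `contained` (logical) and `offset` (0-based integer,
#'   `NA` when not contained).
#' @export
#' @examples
#' seq_contains("UCUACUCGACCUGGUGGUCGAGUGGU", "CUCGACCUGGUGGUCGAGUGGU")
seq_contains <- function(outer, inner) {
  outer <- normalize_seq(outer)
  inner <- normalize_seq(inner)
  if (nchar(inner) > nchar(outer)) {
    return(list(contained = FALSE, offset = NA_integer_))
  }
  pos <- regexpr(inner, outer, fixed = TRUE)
  if (pos > 0L) {
    list(contained = TRUE, offset = as.integer(pos) - 1L)
  } else {
    list(contained = FALSE, offset = NA_integer_)
  }
}

category_rank <- function(category) {
  match(category, c("NONE", "PARTIAL", "NEAR", "EXACT_FULL")) - 1L
}

#' Classify a candidate against a set of host references
#'
#' Runs [best_windowed_match()] (exact / near evidence) and
#' [longest_perfect_stretch()] (partial evidence) against every reference
#' and returns the strongest report under the precedence
#' `EXACT_FULL > NEAR > PARTIAL > NONE`: a full-length near match is
#' stronger evidence of host origin than a short perfect fragment. Within
#' a category, ties resolve to the longest match, then fewest mismatches,
#' then smallest `ref_start`, then reference order.
#'
#' @param candidate Sequence string.
#' @param references Named character vector of reference sequences, or a
#'   data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]).
#' @param cfg A [match_config()].
#' @param candidate_id Identifier copied into the report.
#' @return A one-row match report tibble.
#' @export
classify_host_match <- function(candidate, references, cfg = match_config(),
                                candidate_id = "candidate") {
  refs <- as_reference_tbl(references)
  if (!nrow(refs)) abort("At least one reference is required.")
  candidate <- normalize_seq(candidate)
  reports <- purrr::pmap(
    list(refs$id, refs$seq, seq_len(nrow(refs))),
    function(id, seq, ord) {
      rows <- list()
      if (nchar(candidate) <= nchar(seq)) {
        wm <- best_windowed_match(candidate, seq, cfg,
                                  candidate_id = candidate_id,
                                  reference_id = id)
        if (wm$category != "NONE") rows <- c(rows, list(wm))
      }
      lp <- longest_perfect_stretch(candidate, seq, cfg,
                                    candidate_id = candidate_id,
                                    reference_id = id)
      if (lp$category != "NONE") rows <- c(rows, list(lp))
      if (!length(rows)) return(NULL)
      mutate(bind_rows(rows), .ref_order = ord)
    }
  )
  reports <- bind_rows(reports)
  if (!nrow(reports)) {
    return(match_report_row(candidate_id, NA_character_, "NONE"))
  }
  reports |>
    mutate(.rank = category_rank(.data$category)) |>
    arrange(desc(.data$.rank), desc(.data$matched_length),
            .data$mismatches, .data$ref_start, .data$.ref_order) |>
    slice(1L) |>
    select(-".rank", -".ref_order")
}

#' Classify many candidates against host references
#'
#' Data-frame-first wrapper around [classify_host_match()].
#'
#' @param candidates Data frame with columns `id` and `seq` (e.g. from
#'   [read_fasta()]).
#' @param references Reference set as in [classify_host_match()].
#' @param cfg A [match_config()].
#' @return A tibble with one match report row per candidate.
#' @export
classify_host_matches <- function(candidates, references,
                                  cfg = match_config()) {
  candidates <- as_reference_tbl(candidates)
  purrr::map2(candidates$id, candidates$seq, function(id, seq) {
    classify_host_match(seq, references, cfg, candidate_id = id)
  }) |>
    bind_rows()
}

# accept a named character vector or an id/seq data frame
as_reference_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("ref", seq_along(x))
    return(tibble(id = ids, seq = unname(x)))
  }
  x <- as_tibble(x)
  if (!all(c("id", "seq") %in% names(x))) {
    abort("Sequence table must have columns `id` and `seq`.")
  }
  select(x, "id", "seq")
}
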