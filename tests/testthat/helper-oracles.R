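# Independent brute-force oracles used to cross-check the matchers.
# They work on split character vectors and base string functions only,
# never on the package's integer-coded scanning routines.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Hamming distance of `cand` against every window of `ref` (one strand)
oracle_window_mm <- function(cand, ref) {
  cv <- strsplit(cand, "")[[1L]]
  m <- length(cv)
  n <- nchar(ref)
  if (n < m) return(numeric(0L))
  vapply(0:(n - m), function(s) {
    sum(strsplit(substr(ref, s + 1L, s + m), "")[[1L]] != cv)
  }, numeric(1L))
}

oracle_min_hamming <- function(cand, ref, both_strands = TRUE) {
  mm <- oracle_window_mm(cand, ref)
  if (both_strands) mm <- c(mm, oracle_window_mm(oracle_revcomp(cand), ref))
  if (!length(mm)) Inf else min(mm)
}

# 0-based starts of full-length exact occurrences on the forward strand
oracle_exact_starts <- function(cand, ref) {
  hits <- gregexpr(cand, ref, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0L) else as.integer(hits) - 1L
}

# longest common substring length via exhaustive substring containment
oracle_lcs_len <- function(cand, ref, both_strands = TRUE) {
  probes <- cand
  if (both_strands) probes <- c(probes, oracle_revcomp(cand))
  m <- nchar(cand)
  for (len in m:1) {
    for (p in probes) {
      for (s in 1:(m - len + 1L)) {
        if (grepl(substr(p, s, s + len - 1L), ref, fixed = TRUE)) {
          return(len)
        }
      }
    }
  }
  0L
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random long count table (candidates x samples)
random_count_tbl <- function(n_cand, n_samp, lambda = 2) {
  tidyr::expand_grid(
    candidate_id = sprintf("c%02d", seq_len(n_cand)),
    sample_id = sprintf("s%03d", seq_len(n_samp))
  ) |>
    dplyr::mutate(count = stats::rpois(dplyr::n(), lambda))
}

toy_annotation <- function(candidate_id, in_mirbase = FALSE,
                           biotype = "UNKNOWN") {
  tibble::tibble(
    candidate_id = candidate_id,
    sequence = "ACGUACGUACGUACGUACGU",
    in_current_mirbase = in_mirbase,
    plant_biotype = biotype,
    claimed_species = "Arabidopsis thaliana"
  )
}

match_row <- function(candidate_id, category) {
  tibble::tibble(candidate_id = candidate_id, category = category)
}
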