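#' Read a FASTA file of candidates or references
#'
#' Records keep their file order; ids are taken from the header up to the
#' first whitespace; sequences are normalized via [normalize_seq()] (RNA
#' and DNA alphabets both accepted).
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  if (!length(set)) abort(paste0("FASTA file is empty: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("Duplicated FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- unname(normalize_seq(stats::setNames(as.character(set), ids)))
  tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param sequences `id`/`seq` data frame or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  tbl <- as_reference_tbl(sequences)
  set <- Biostrings::DNAStringSet(stats::setNames(tbl$seq, tbl$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a small-RNA read set (FASTA or FASTQ)
#'
#' Qualities are ignored; the format is chosen from the file extension
#' (`.fastq`/`.fq`, optionally gzipped, is FASTQ; anything else FASTA).
#'
#' @param path Path to the read file.
#' @param cfg A [filter_config()]; reads outside its length range are
#'   rejected.
#' @return A read-set tibble with `read_id` and `seq`.
#' @export
read_reads <- function(path, cfg = filter_config()) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  set <- tryCatch(
    Biostrings::readBStringSet(path,
                               format = if (fastq) "fastq" else "fasta"),
    error = function(e) {
      abort(paste0("Malformed read file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  if (!length(set)) abort(paste0("Read file is empty: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) abort("Duplicated read ids in read file.")
  validate_reads(tibble(read_id = ids, seq = unname(as.character(set))), cfg)
}

#' Read a candidate-by-sample count table (TSV)
#'
#' The on-disk dialect is wide: first column candidate id, one column per
#' sample, header row of sample ids, integer cells. Blank cells are read
#' as 0 (a candidate absent from a sample has count 0, never missing).
#'
#' @param path Path to a TSV file.
#' @return A long count table (see [validate_counts()]).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  wide <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(wide) < 2L) {
    abort("Count table needs a candidate column and at least one sample.")
  }
  names(wide)[1L] <- "candidate_id"
  if (anyDuplicated(wide$candidate_id)) {
    abort("Duplicated candidate id in count table.")
  }
  if (anyDuplicated(names(wide))) {
    abort("Duplicated sample id in count table header.")
  }
  long <- tidyr::pivot_longer(wide, -"candidate_id",
                              names_to = "sample_id",
                              values_to = "raw")
  long$raw[is.na(long$raw) | long$raw == ""] <- "0"
  bad <- !grepl("^[0-9]+$", long$raw)
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf(
      "Non-integer count '%s' for candidate '%s', sample '%s'.",
      long$raw[i], long$candidate_id[i], long$sample_id[i]))
  }
  validate_counts(tibble(
    candidate_id = long$candidate_id,
    sample_id = long$sample_id,
    count = as.integer(long$raw)
  ))
}

#' Write a long count table as wide TSV
#'
#' @param counts Long count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_counts(counts)
  wide <- tidyr::pivot_wider(counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata (TSV)
#'
#' Columns `sample_id`, `library_id`, `study`, `sample_type`,
#' `total_reads` (blank allowed).
#'
#' @param path Path to a TSV file.
#' @return A validated metadata tibble.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    library_id = readr::col_character(),
    study = readr::col_character(),
    sample_type = readr::col_character(),
    total_reads = readr::col_double()
  ), progress = FALSE)
  validate_sample_meta(meta)
}

#' Read a candidate annotation table (TSV)
#'
#' Columns `candidate_id`, `sequence`, `in_current_mirbase`,
#' `plant_biotype`, `claimed_species`.
#'
#' @param path Path to a TSV file.
#' @return A validated annotation tibble.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(
    candidate_id = readr::col_character(),
    sequence = readr::col_character(),
    in_current_mirbase = readr::col_logical(),
    plant_biotype = readr::col_character(),
    claimed_species = readr::col_character()
  ), progress = FALSE)
  validate_annotations(ann)
}

#' Write result tables with a checksum manifest
#'
#' Writes each table in a named list as `<name>.tsv` into `dir` (staged to
#' a temporary name, then renamed, so failed runs leave no partial file)
#' and writes `manifest.tsv` listing every artifact with its MD5 checksum
#' and row count. Rerunning with identical inputs reproduces identical
#' checksums.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_outputs <- function(tables, dir) {
  if (is.null(names(tables)) && length(tables)) {
    abort("`tables` must be a named list.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("Cannot create directory: ", dir))
  files <- character(0L)
  for (nm in names(tables)) {
    target <- file.path(dir, paste0(nm, ".tsv"))
    stage <- paste0(target, ".tmp")
    readr::write_tsv(as_tibble(tables[[nm]]), stage, progress = FALSE)
    if (!file.rename(stage, target)) {
      abort(paste0("Cannot write output file: ", target))
    }
    files <- c(files, target)
  }
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    n_rows = vapply(tables, nrow, integer(1L), USE.NAMES = FALSE)
  )
  stage <- file.path(dir, "manifest.tsv.tmp")
  readr::write_tsv(manifest, stage, progress = FALSE)
  file.rename(stage, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
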