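# plain-text readers/writers for the pipeline's tables and sequence files

#' Write / read a crRNA library table
#'
#' Tab-separated with a header, UTF-8, stable (gene, rank) row order; logical
#' flags are serialized as `true`/`false` literals.
#'
#' @param records Library tibble as produced by [design_library()].
#' @param path Output TSV path.
#' @return `write_library_table()` returns the path invisibly;
#'   `read_library_table()` returns the library tibble.
#' @export
write_library_table <- function(records, path) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "`records` must be a non-empty data frame")
  cols <- c("crRNA_id", "gene_id", "transcript_id", "spacer_seq", "oligo_seq",
            "is_control", "design_stage", "below_minimum")
  assert_columns(records, cols, "records")
  out <- records[, cols]
  out$is_control <- ifelse(out$is_control, "true", "false")
  out$below_minimum <- ifelse(out$below_minimum, "true", "false")
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) abort(sprintf("failed to write library table to '%s': %s",
                                      path, conditionMessage(e)))
  )
  invisible(path)
}

#' @rdname write_library_table
#' @export
read_library_table <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path))
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      crRNA_id = readr::col_character(),
      gene_id = readr::col_character(),
      transcript_id = readr::col_character(),
      spacer_seq = readr::col_character(),
      oligo_seq = readr::col_character(),
      is_control = readr::col_character(),
      design_stage = readr::col_character(),
      below_minimum = readr::col_character()
    ),
    progress = FALSE
  )
  tab$is_control <- tab$is_control == "true"
  tab$below_minimum <- tab$below_minimum == "true"
  tab
}

#' Write / read a guide count table
#'
#' Guides in rows (crRNA_id, gene_id, is_control) and one column per sample.
#'
#' @param counts Wide count tibble.
#' @param path TSV path.
#' @return The path invisibly, or the count tibble.
#' @export
write_counts <- function(counts, path) {
  assert_columns(counts, "crRNA_id", "counts")
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write reference sequences as FASTA
#'
#' @param sequences Named character vector, tibble (ref_id, sequence) or
#'   `DNAStringSet`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  refs <- normalize_references(sequences)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), path)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read gene intervals as BED
#'
#' 0-based half-open intervals; the BED name field carries the gene id.
#'
#' @param intervals Tibble with ref_id, start, end, gene_id.
#' @param path BED path.
#' @return The path invisibly, or the interval tibble.
#' @export
write_bed <- function(intervals, path) {
  assert_columns(intervals, c("ref_id", "start", "end", "gene_id"), "intervals")
  readr::write_tsv(intervals[, c("ref_id", "start", "end", "gene_id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path))
  readr::read_tsv(path, col_names = c("ref_id", "start", "end", "gene_id"),
                  col_types = "ciic", progress = FALSE)
}

# read a plain 4-line-record FASTQ, with record-level validation so that a
# malformed record is reported with its line number
read_fastq_sequences <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) return(character(0))
  assert_that(n %% 4 == 0,
              sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4", path, n))
  heads <- seq(1, n, by = 4)
  bad_head <- heads[!startsWith(lines[heads], "@")]
  assert_that(length(bad_head) == 0,
              sprintf("malformed FASTQ '%s': header at line %d does not start with '@'",
                      path, bad_head[1]))
  plus <- heads + 2L
  bad_plus <- plus[!startsWith(lines[plus], "+")]
  assert_that(length(bad_plus) == 0,
              sprintf("malformed FASTQ '%s': separator at line %d does not start with '+'",
                      path, bad_plus[1]))
  seq_idx <- heads + 1L
  bad_q <- seq_idx[nchar(lines[seq_idx]) != nchar(lines[seq_idx + 2L])]
  assert_that(length(bad_q) == 0,
              sprintf("malformed FASTQ '%s': quality length mismatch for read at line %d",
                      path, bad_q[1] - 1L))
  toupper(lines[seq_idx])
}

#' Write a QC report as JSON
#'
#' @param qc A [screen_qc()] result.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  assert_that(inherits(qc, "cas13_qc"), "`qc` must come from screen_qc()")
  jsonlite::write_json(
    list(sample_stats = qc$sample_stats, correlations = qc$correlations,
         min_correlation = qc$min_correlation),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
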