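# internal argument checks and small sequence helpers

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "cas13screen_error")
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min,
    sprintf("`%s` must be a single integer >= %d", name, min)
  )
}

assert_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) && x <= max
  assert_that(ok, sprintf("`%s` must be a single number in the valid range", name))
}

assert_seed <- function(seed) {
  assert_that(
    is.numeric(seed) && length(seed) == 1L && is.finite(seed) && seed == as.integer(seed),
    "`seed` must be a single integer"
  )
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  assert_that(
    length(missing) == 0L,
    sprintf("`%s` is missing column(s): %s", name, paste(missing, collapse = ", "))
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalize reference input (named character vector, tibble, or DNAStringSet)
# to a named character vector of upper-case sequences
normalize_references <- function(references) {
  if (inherits(references, "DNAStringSet")) {
    refs <- as.character(references)
  } else if (is.data.frame(references)) {
    assert_columns(references, c("ref_id", "sequence"), "references")
    refs <- setNames(as.character(references$sequence), references$ref_id)
  } else if (is.character(references)) {
    refs <- references
  } else {
    abort("`references` must be a named character vector, a data frame with ref_id/sequence, or a DNAStringSet")
  }
  assert_that(!is.null(names(refs)) && !anyNA(names(refs)) && !any(names(refs) == ""),
              "references must be named")
  assert_that(!anyDuplicated(names(refs)), "reference names must be unique")
  toupper(refs)
}

# numeric sample columns of a wide count table (everything except guide metadata)
count_columns <- function(counts) {
  meta <- c("crRNA_id", "gene_id", "is_control", "transcript_id")
  setdiff(names(counts), meta)
}

count_matrix <- function(counts, samples = NULL) {
  cols <- samples %||% count_columns(counts)
  assert_columns(counts, cols, "counts")
  m <- as.matrix(counts[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$crRNA_id
  m
}
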