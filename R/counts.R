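# guide quantification from reads and the screen's count-level QC

#' Count guide spacers in a FASTQ file
#'
#' Per read, the first exact occurrence of `flank5` is located, the following
#' `guide_length` bases are extracted, and the exactly matching library
#' spacer is incremented. Reads with no flank, a truncated spacer region, or
#' an unknown spacer are discarded and tallied by reason. No mismatch rescue
#' is attempted: a single mismatch inside the spacer discards the read.
#'
#' @param fastq Path to a FASTQ file (4-line records).
#' @param library Library tibble with unique `crRNA_id` and `spacer_seq`.
#' @param flank5 Non-empty 5' anchor sequence.
#' @return A list: `counts` (tibble crRNA_id, count — zero rows kept),
#'   `total_reads`, `assigned`, `match_rate`, and `discarded` (tibble
#'   reason/n). An empty FASTQ yields an all-zero column with a warning.
#' @export
count_reads <- function(fastq, library, flank5) {
  assert_columns(library, c("crRNA_id", "spacer_seq"), "library")
  assert_that(!anyDuplicated(library$spacer_seq), "library spacers must be unique")
  assert_that(is.character(flank5) && length(flank5) == 1L && nzchar(flank5),
              "`flank5` must be a non-empty string")
  guide_length <- unique(nchar(library$spacer_seq))
  assert_that(length(guide_length) == 1L, "library spacers must share one length")

  reads <- read_fastq_sequences(fastq)
  total <- length(reads)
  lookup <- setNames(library$crRNA_id, library$spacer_seq)

  if (total == 0) {
    warn(sprintf("empty FASTQ '%s': returning an all-zero count column", fastq))
    spacers <- character(0)
  }
  pos <- if (total > 0) regexpr(flank5, reads, fixed = TRUE) else integer(0)
  no_flank <- pos < 0
  spacer_start <- pos + nchar(flank5)
  truncated <- !no_flank & (spacer_start + guide_length - 1L > nchar(reads))
  candidate <- !no_flank & !truncated
  spacers <- substring(reads[candidate], spacer_start[candidate],
                       spacer_start[candidate] + guide_length - 1L)
  hit <- lookup[spacers]
  unknown_n <- sum(is.na(hit))
  assigned_ids <- hit[!is.na(hit)]

  tab <- table(factor(assigned_ids, levels = library$crRNA_id))
  counts <- tibble(crRNA_id = library$crRNA_id, count = as.numeric(tab))
  assigned <- length(assigned_ids)
  list(
    counts = counts,
    total_reads = total,
    assigned = assigned,
    match_rate = if (total > 0) assigned / total else NA_real_,
    discarded = tibble(
      reason = c("no_flank", "truncated_spacer", "unknown_spacer"),
      n = c(sum(no_flank), sum(truncated), unknown_n)
    )
  )
}

#' Gini index of a count vector
#'
#' Library-evenness statistic: `G = (2 * sum(i * x_(i))) / (n * sum(x)) -
#' (n + 1) / n` with `x_(i)` ascending, equal to the mean absolute pairwise
#' difference divided by twice the mean. 0 means perfectly even counts; an
#' even, well-transduced screen library stays below 0.1.
#'
#' @param x Non-negative numeric vector with at least two entries and a
#'   positive sum.
#' @return The Gini index, in `[0, 1 - 1/n]`.
#' @export
#' @examples
#' gini(c(5, 5, 5, 5))
#' gini(c(0, 0, 0, 4))
gini <- function(x) {
  assert_that(is.numeric(x) && length(x) >= 2, "`x` must have at least two entries")
  assert_that(all(is.finite(x)) && all(x >= 0), "`x` must be non-negative and finite")
  assert_that(sum(x) > 0, "`x` must not be all zero")
  x <- sort(as.numeric(x))
  n <- length(x)
  (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
}

#' Pairwise replicate correlations on log counts
#'
#' Pearson correlation of `log2(count + 1)` between every pair of the given
#' samples. A zero-variance sample yields `NA` for its pairs (reported, not
#' dropped).
#'
#' @param counts Wide count tibble.
#' @param sample_ids At least two sample column names forming the replicate
#'   group.
#' @return Tibble: sample_a, sample_b, r — plus the group minimum as the
#'   `min_r` attribute.
#' @export
replicate_correlation <- function(counts, sample_ids) {
  assert_that(is.character(sample_ids) && length(sample_ids) >= 2,
              "`sample_ids` must name at least two samples")
  m <- count_matrix(counts, sample_ids)
  lm2 <- log2(m + 1)
  pairs <- utils::combn(sample_ids, 2)
  r <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- lm2[, pairs[1, j]]
    b <- lm2[, pairs[2, j]]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  out <- tibble(sample_a = pairs[1, ], sample_b = pairs[2, ], r = r)
  attr(out, "min_r") <- if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)
  out
}

#' Median-ratio count normalization
#'
#' Size factor per sample = median, over guides with nonzero counts in every
#' sample, of that guide's count divided by its geometric mean across
#' samples; size factors are then rescaled to geometric mean 1 (so the
#' operation is idempotent) and normalized counts are counts divided by the
#' size factor.
#'
#' @param counts Wide count tibble.
#' @param sample_ids Sample columns to normalize (default: all).
#' @return A list: `normalized` (tibble with the sample columns replaced) and
#'   `size_factors` (named numeric).
#' @export
median_ratio_normalize <- function(counts, sample_ids = NULL) {
  sample_ids <- sample_ids %||% count_columns(counts)
  m <- count_matrix(counts, sample_ids)
  pos <- rowSums(m > 0) == ncol(m)
  assert_that(any(pos),
              "no guide has nonzero counts in every sample; add a pseudocount upstream")
  gm <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / gm, 2, median)
  # scale factors to geometric mean 1 so normalization is idempotent
  sf <- sf / exp(mean(log(sf)))
  norm <- counts
  for (s in sample_ids) norm[[s]] <- counts[[s]] / sf[s]
  list(normalized = norm, size_factors = sf)
}

#' Screen count quality control
#'
#' Computes the two count-level QC statistics of a pooled screen — the Gini
#' index of each sample's guide counts (library evenness / over-selection)
#' and all pairwise replicate Pearson correlations on log2(count + 1) within
#' each timepoint group — plus totals and any per-sample match rates.
#'
#' @param counts Wide count tibble.
#' @param samples Sample metadata tibble (sample_id, timepoint, replicate),
#'   as from [simulate_screen()]; optional `match_rate` column is carried
#'   through.
#' @return A `cas13_qc` object with `sample_stats`, `correlations` and
#'   `min_correlation`; see [glance.cas13_qc()].
#' @export
screen_qc <- function(counts, samples) {
  assert_columns(samples, c("sample_id", "timepoint"), "samples")
  assert_that(all(samples$sample_id %in% names(counts)),
              "every sample_id must be a column of `counts`")
  sample_stats <- samples %>%
    dplyr::mutate(
      total_reads = vapply(.data$sample_id, function(s) sum(counts[[s]]), numeric(1)),
      gini = vapply(.data$sample_id, function(s) gini(counts[[s]]), numeric(1))
    )
  correlations <- samples %>%
    dplyr::group_by(.data$timepoint) %>%
    dplyr::filter(dplyr::n() >= 2) %>%
    dplyr::group_map(function(grp, key) {
      rc <- replicate_correlation(counts, grp$sample_id)
      dplyr::mutate(rc, timepoint = key$timepoint)
    }) %>%
    dplyr::bind_rows()
  min_r <- if (nrow(correlations) > 0 && !all(is.na(correlations$r))) {
    min(correlations$r, na.rm = TRUE)
  } else {
    NA_real_
  }
  structure(
    list(sample_stats = sample_stats, correlations = correlations,
         min_correlation = min_r),
    class = "cas13_qc"
  )
}

#' @export
print.cas13_qc <- function(x, ...) {
  cat("Pooled screen count QC\n")
  cat(sprintf("  samples: %d, max Gini %.4f, min replicate r %.4f\n",
              nrow(x$sample_stats), max(x$sample_stats$gini),
              x$min_correlation))
  invisible(x)
}
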