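# off-target discovery: seeded scanner (production) and exhaustive brute-force
# oracle, plus the library filter driven by their hits

validate_scan_inputs <- function(library, references, annotation, config) {
  assert_that(inherits(config, "cas13_scan_config"), "`config` must come from scan_config()")
  assert_columns(library, c("crRNA_id", "gene_id", "spacer_seq"), "library")
  assert_that(nrow(library) >= 1, "`library` must be non-empty")
  assert_that(!anyDuplicated(library$crRNA_id), "crRNA_id values must be unique")
  assert_that(all(grepl("^[ACGT]+$", library$spacer_seq)),
              "spacer sequences must be non-empty ACGT strings")
  assert_columns(annotation, c("ref_id", "start", "end", "gene_id"), "annotation")
  refs <- normalize_references(references)
  lmin <- min_aligned_length(nchar(library$spacer_seq), config$min_coverage)
  assert_that(all(nchar(library$spacer_seq) >= lmin),
              "guides must be at least the minimum aligned length")
  k_bound <- min(lmin %/% (config$max_mismatches + 1L))
  k <- config$seed_kmer_length %||% k_bound
  assert_that(k >= 1, "minimum aligned length too short for the mismatch budget")
  assert_that(k <= k_bound,
              sprintf("`seed_kmer_length` must be <= %d (pigeonhole bound) or hits may be missed", k_bound))
  list(refs = refs, k = as.integer(k))
}

# raw C++ placements -> OffTargetHit tibble: attach ids, drop placements
# overlapping the guide's own gene intervals, then collapse nested placements
# per (crRNA, ref, start, strand) keeping the longest, then fewest mismatches
finalize_hits_dplyr <- function(raw, library, refs, annotation, config) {
  hits <- as_tibble(raw) %>%
    dplyr::mutate(
      crRNA_id = library$crRNA_id[.data$guide_idx],
      gene_id = library$gene_id[.data$guide_idx],
      guide_length = nchar(library$spacer_seq)[.data$guide_idx],
      ref_id = names(refs)[.data$ref_idx]
    )
  own <- hits %>%
    dplyr::inner_join(annotation, by = c("gene_id", "ref_id"),
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$start < .data$ref_start + .data$aligned_length,
                  .data$end > .data$ref_start) %>%
    dplyr::distinct(.data$guide_idx, .data$ref_idx, .data$strand,
                    .data$ref_start, .data$guide_offset, .data$aligned_length)
  hits %>%
    dplyr::anti_join(own, by = c("guide_idx", "ref_idx", "strand", "ref_start",
                                 "guide_offset", "aligned_length")) %>%
    # collapse nested placements per locus; the locus anchor is the guide's
    # 5' end (ref_start on "+", alignment end on "-") so that hit sets are
    # symmetric under reverse-complementing the reference
    dplyr::mutate(anchor = ifelse(.data$strand == "+", .data$ref_start,
                                  .data$ref_start + .data$aligned_length)) %>%
    dplyr::group_by(.data$crRNA_id, .data$ref_id, .data$anchor, .data$strand) %>%
    dplyr::arrange(dplyr::desc(.data$aligned_length), .data$mismatches,
                   .data$guide_offset, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(coverage = .data$aligned_length / .data$guide_length) %>%
    dplyr::select("crRNA_id", "ref_id", "strand", "ref_start", "guide_offset",
                  "aligned_length", "mismatches", "coverage") %>%
    dplyr::arrange(.data$crRNA_id, .data$ref_id, .data$ref_start, .data$strand)
}

empty_hits <- function() {
  tibble(crRNA_id = character(0), ref_id = character(0), strand = character(0),
         ref_start = integer(0), guide_offset = integer(0),
         aligned_length = integer(0), mismatches = integer(0),
         coverage = numeric(0))
}

#' Scan a library for off-target complementarity
#'
#' Finds every placement of a contiguous guide substring covering at least
#' `min_coverage` of the guide (>= 21 nt for 23-mers at 90%) against any
#' reference window with at most `max_mismatches` mismatches, excluding
#' placements inside the guide's own gene intervals. Matching is ungapped and
#' performed in target-site sequence space; with `scan_both_strands = TRUE`
#' the reverse complement of each reference is scanned as well and hits are
#' reported on strand `-` in forward coordinates. Nested placements at one
#' locus collapse to the longest (then fewest-mismatch) placement.
#'
#' The production scanner seeds candidate alignments with exact k-mers (by
#' the pigeonhole principle any qualifying placement contains an exact seed
#' of `floor(min_aligned_length / (max_mismatches + 1))` bases) and verifies
#' them by Hamming extension; its output is identical to [brute_force_scan()].
#'
#' @param library Library tibble with `crRNA_id`, `gene_id`, `spacer_seq`.
#' @param references Named character vector, tibble (ref_id, sequence) or
#'   `DNAStringSet`.
#' @param annotation Interval tibble (ref_id, start, end, gene_id; 0-based
#'   half-open) locating each gene, used for self-exclusion.
#' @param config A [scan_config()].
#' @return Hit tibble: crRNA_id, ref_id, strand, ref_start, guide_offset,
#'   aligned_length, mismatches, coverage.
#' @export
scan_offtargets <- function(library, references, annotation, config = scan_config()) {
  v <- validate_scan_inputs(library, references, annotation, config)
  raw <- cpp_seeded_scan(unname(v$refs), library$spacer_seq, v$k,
                         config$max_mismatches, config$min_coverage,
                         config$scan_both_strands)
  if (nrow(raw) == 0) return(empty_hits())
  finalize_hits_dplyr(raw, library, v$refs, annotation, config)
}

#' Exhaustive off-target scan (oracle)
#'
#' Enumerates every (guide substring, reference window, strand) placement and
#' applies exactly the filtering, self-exclusion and collapsing rules of
#' [scan_offtargets()]. Quadratic and meant for verification; the seeded
#' scanner must produce an identical hit set.
#'
#' @inheritParams scan_offtargets
#' @return Hit tibble with the same columns as [scan_offtargets()].
#' @export
brute_force_scan <- function(library, references, annotation, config = scan_config()) {
  v <- validate_scan_inputs(library, references, annotation, config)
  raw <- cpp_brute_scan(unname(v$refs), library$spacer_seq,
                        config$max_mismatches, config$min_coverage,
                        config$scan_both_strands)
  if (nrow(raw) == 0) return(empty_hits())
  # base-R exclusion and collapse, independent of the dplyr path used by the
  # production scanner
  raw <- as.data.frame(raw)
  raw$crRNA_id <- library$crRNA_id[raw$guide_idx]
  raw$gene_id <- library$gene_id[raw$guide_idx]
  raw$guide_length <- nchar(library$spacer_seq)[raw$guide_idx]
  raw$ref_id <- names(v$refs)[raw$ref_idx]

  ann <- as.data.frame(annotation)
  keep <- vapply(seq_len(nrow(raw)), function(i) {
    iv <- ann[ann$gene_id == raw$gene_id[i] & ann$ref_id == raw$ref_id[i], , drop = FALSE]
    if (nrow(iv) == 0) return(TRUE)
    !any(iv$start < raw$ref_start[i] + raw$aligned_length[i] & iv$end > raw$ref_start[i])
  }, logical(1))
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0) return(empty_hits())

  raw$anchor <- ifelse(raw$strand == "+", raw$ref_start,
                       raw$ref_start + raw$aligned_length)
  ord <- order(raw$crRNA_id, raw$ref_id, raw$anchor, raw$strand,
               -raw$aligned_length, raw$mismatches, raw$guide_offset)
  raw <- raw[ord, , drop = FALSE]
  key <- paste(raw$crRNA_id, raw$ref_id, raw$anchor, raw$strand, sep = "\r")
  raw <- raw[!duplicated(key), , drop = FALSE]
  raw$coverage <- raw$aligned_length / raw$guide_length
  out <- raw[order(raw$crRNA_id, raw$ref_id, raw$ref_start, raw$strand),
             c("crRNA_id", "ref_id", "strand", "ref_start", "guide_offset",
               "aligned_length", "mismatches", "coverage")]
  rownames(out) <- NULL
  as_tibble(out)
}

#' Remove guides with off-target hits from a library
#'
#' Every crRNA with at least one reported hit is dropped; the rest of the
#' table is returned unchanged. The removal report lists, per removed guide,
#' the number of hits and its worst hit (fewest mismatches, then longest
#' alignment).
#'
#' @param library Library tibble.
#' @param hits Hit tibble from [scan_offtargets()] or [brute_force_scan()]
#'   produced against the same library.
#' @return A list: `retained` (library rows without hits) and `removed`
#'   (report tibble: crRNA_id, n_hits, worst_* columns).
#' @export
filter_library <- function(library, hits) {
  assert_columns(library, "crRNA_id", "library")
  assert_columns(hits, c("crRNA_id", "ref_id", "strand", "ref_start",
                         "aligned_length", "mismatches", "coverage"), "hits")
  unknown <- setdiff(hits$crRNA_id, library$crRNA_id)
  assert_that(length(unknown) == 0,
              sprintf("hits reference crRNA id(s) not in the library: %s",
                      paste(head(unknown, 5), collapse = ", ")))
  removed <- hits %>%
    dplyr::group_by(.data$crRNA_id) %>%
    dplyr::arrange(.data$mismatches, dplyr::desc(.data$aligned_length),
                   .data$ref_id, .data$ref_start, .by_group = TRUE) %>%
    dplyr::summarise(
      n_hits = dplyr::n(),
      worst_ref_id = .data$ref_id[1],
      worst_strand = .data$strand[1],
      worst_ref_start = .data$ref_start[1],
      worst_aligned_length = .data$aligned_length[1],
      worst_mismatches = .data$mismatches[1],
      worst_coverage = .data$coverage[1],
      .groups = "drop"
    )
  retained <- library[!library$crRNA_id %in% removed$crRNA_id, , drop = FALSE]
  if (nrow(retained) == 0) warn("all guides were removed by the off-target filter")
  list(retained = retained, removed = removed)
}
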