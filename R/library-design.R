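# crRNA library design: per-transcript quartile labelling, staged greedy
# selection with quality/overlap relaxation, redundancy removal, flanks

#' Assign quality quartiles per transcript
#'
#' Quartile boundaries are the 25th/50th/75th linear-interpolation
#' percentiles of each transcript's own candidate scores. Quartile 4 (top)
#' means score >= the 75th percentile; ties at a boundary resolve upward, so
#' a transcript whose scores are all equal is entirely quartile 4.
#' Transcripts with fewer than four candidates are all labelled quartile 4.
#'
#' @param candidates Candidate tibble with `transcript_id` and
#'   `quality_score` columns; scores must be finite.
#' @return The input with a `quartile` integer column added.
#' @export
#' @examples
#' assign_quartiles(tibble::tibble(
#'   transcript_id = "T1", gene_id = "G1", start = c(0, 30, 60, 90),
#'   target_site_seq = "A", quality_score = c(0.1, 0.4, 0.6, 0.9)
#' ))$quartile
assign_quartiles <- function(candidates) {
  assert_columns(candidates, c("transcript_id", "quality_score"), "candidates")
  assert_that(nrow(candidates) >= 1, "`candidates` must be non-empty")
  assert_that(all(is.finite(candidates$quality_score)),
              "quality scores must be finite")
  candidates %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::mutate(quartile = {
      s <- .data$quality_score
      if (length(s) < 4L) {
        rep(4L, length(s))
      } else {
        q <- quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        1L + (s >= q[1]) + (s >= q[2]) + (s >= q[3])
      }
    }) %>%
    dplyr::ungroup()
}

# interval overlap in nucleotides between [s1, s1+l1) and [s2, s2+l2)
overlap_nt <- function(s1, l1, s2, l2) {
  pmax(0L, pmin(s1 + l1, s2 + l2) - pmax(s1, s2))
}

# greedy pass: candidates already restricted to the admissible quartiles,
# ordered by (score desc, start asc, sequence); accept while the pairwise
# overlap with every accepted guide stays <= max_overlap
greedy_select <- function(cand, guide_length, target, max_overlap) {
  ord <- order(-cand$quality_score, cand$start, cand$target_site_seq)
  cand <- cand[ord, , drop = FALSE]
  picked <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(picked) >= target) break
    ok <- !length(picked) || all(
      overlap_nt(cand$start[i], guide_length, cand$start[picked], guide_length) <= max_overlap
    )
    if (ok) picked <- c(picked, i)
  }
  cand[picked, , drop = FALSE]
}

#' Staged guide selection for one transcript
#'
#' Runs the staged greedy selection: (strict) non-overlapping top-quartile
#' candidates in score order, capped at `target_per_transcript`; if fewer
#' than `min_guides` survive, (relaxed_q3) re-run admitting candidates down
#' to quartile `relax_quartile_min` still with zero overlap; if still short,
#' (relaxed_overlap) re-run tolerating pairwise overlaps up to
#' `relax_overlap_max_nt`. The first stage reaching `min_guides` wins;
#' otherwise the last stage's result is returned with `below_minimum = TRUE`
#' (any count >= 1 is kept).
#'
#' @param candidates Candidates of a single transcript, with quartiles
#'   assigned (see [assign_quartiles()]).
#' @param config A [design_config()].
#' @return A list: `selected` (candidate tibble in selection order),
#'   `design_stage` (`"strict"`, `"relaxed_q3"` or `"relaxed_overlap"`), and
#'   `below_minimum` flag.
#' @export
select_guides_for_transcript <- function(candidates, config = design_config()) {
  assert_that(inherits(config, "cas13_design_config"), "`config` must come from design_config()")
  assert_columns(candidates,
                 c("transcript_id", "start", "target_site_seq", "quality_score", "quartile"),
                 "candidates")
  assert_that(nrow(candidates) >= 1, "`candidates` must be non-empty")
  assert_that(dplyr::n_distinct(candidates$transcript_id) == 1L,
              "`candidates` must come from a single transcript")
  L <- config$guide_length
  target <- config$target_per_transcript

  stages <- list(
    strict = list(cand = candidates[candidates$quartile == 4L, , drop = FALSE], ov = 0L),
    relaxed_q3 = list(
      cand = candidates[candidates$quartile >= config$relax_quartile_min, , drop = FALSE],
      ov = 0L
    ),
    relaxed_overlap = list(
      cand = candidates[candidates$quartile >= config$relax_quartile_min, , drop = FALSE],
      ov = config$relax_overlap_max_nt
    )
  )
  result <- NULL
  stage_name <- NA_character_
  for (nm in names(stages)) {
    sel <- greedy_select(stages[[nm]]$cand, L, target, stages[[nm]]$ov)
    result <- sel
    stage_name <- nm
    if (nrow(sel) >= config$min_guides) break
  }
  list(
    selected = as_tibble(result),
    design_stage = stage_name,
    below_minimum = nrow(result) < config$min_guides
  )
}

#' Design a synthesis-ready crRNA library
#'
#' Assigns quartiles, runs the staged selection per transcript, removes
#' redundancy, and emits synthesis oligos. Redundancy rules: exact duplicate
#' spacers within one gene collapse to a single record; a spacer selected for
#' two different genes is removed entirely (it cannot be attributed). Control
#' genes are flagged, guides are ranked by score within each gene
#' (`crRNA_id = <gene>_<rank>`), and the oligo is `flank5 + spacer + flank3`.
#' The spacer column stores the target-site (protospacer) sequence by
#' default; set `spacer_as = "reverse_complement"` in the config to emit the
#' crRNA spacer orientation instead.
#'
#' @param candidates Candidate tibble (transcript_id, gene_id, start,
#'   target_site_seq, quality_score); quartiles are (re)assigned internally.
#' @param controls Character vector of control gene ids.
#' @param config A [design_config()].
#' @return A library tibble: crRNA_id, gene_id, transcript_id, spacer_seq,
#'   oligo_seq, is_control, design_stage, below_minimum.
#' @export
#' @examples
#' tx <- simulate_transcriptome(3, c(300, 400), seed = 1)
#' cand <- simulate_guide_scores(tx$transcripts, seed = 2)
#' lib <- design_library(cand)
#' table(lib$gene_id)
design_library <- function(candidates, controls = character(0), config = design_config()) {
  assert_that(inherits(config, "cas13_design_config"), "`config` must come from design_config()")
  assert_columns(candidates,
                 c("transcript_id", "gene_id", "start", "target_site_seq", "quality_score"),
                 "candidates")
  assert_that(nrow(candidates) >= 1, "`candidates` must cover at least one transcript")
  bad_len <- nchar(candidates$target_site_seq) != config$guide_length
  assert_that(!any(bad_len), "all target_site_seq must have length `guide_length`")

  candidates <- assign_quartiles(candidates)
  gene_of <- candidates %>%
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  assert_that(!anyDuplicated(gene_of$transcript_id),
              "each transcript must map to a single gene")

  per_tx <- candidates %>%
    dplyr::group_split(.data$transcript_id) %>%
    purrr::map(function(tx_cand) {
      res <- select_guides_for_transcript(tx_cand, config)
      if (nrow(res$selected) == 0) {
        warn(sprintf("transcript %s yielded no selectable guide and was skipped",
                     tx_cand$transcript_id[1]))
        return(NULL)
      }
      dplyr::mutate(res$selected,
                    design_stage = res$design_stage,
                    below_minimum = res$below_minimum)
    }) %>%
    purrr::compact() %>%
    dplyr::bind_rows()
  assert_that(nrow(per_tx) > 0, "no transcript yielded selectable guides")

  records <- per_tx %>%
    # same-gene exact duplicates collapse to the best-scoring record
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$quality_score),
                   .data$start, .data$transcript_id) %>%
    dplyr::distinct(.data$gene_id, .data$target_site_seq, .keep_all = TRUE) %>%
    # cross-gene duplicates are dropped entirely
    dplyr::group_by(.data$target_site_seq) %>%
    dplyr::filter(dplyr::n_distinct(.data$gene_id) == 1L) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::arrange(dplyr::desc(.data$quality_score), .data$start,
                   .data$target_site_seq, .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()

  spacer <- if (config$spacer_as == "reverse_complement") {
    revcomp(records$target_site_seq)
  } else {
    records$target_site_seq
  }
  out <- tibble(
    crRNA_id = paste0(records$gene_id, "_", records$rank),
    gene_id = records$gene_id,
    transcript_id = records$transcript_id,
    spacer_seq = spacer,
    oligo_seq = paste0(config$flank5, spacer, config$flank3),
    is_control = records$gene_id %in% controls,
    design_stage = records$design_stage,
    below_minimum = records$below_minimum
  ) %>%
    dplyr::arrange(.data$gene_id, as.integer(sub(".*_", "", .data$crRNA_id)))
  assert_that(!anyDuplicated(out$crRNA_id), "internal error: duplicate crRNA_id")
  out
}
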