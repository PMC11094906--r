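test_that("quartile labels follow per-transcript percentile boundaries", {
  set.seed(1)
  q <- assign_quartiles(make_candidates(c(0, 30, 60, 90), c(0.1, 0.4, 0.6, 0.9)))
  expect_equal(q$quartile, 1:4)

  ties <- assign_quartiles(make_candidates(seq(0, 90, 30), rep(0.5, 4)))
  expect_equal(ties$quartile, rep(4L, 4))

  single <- assign_quartiles(make_candidates(0, 0.2))
  expect_equal(single$quartile, 4L)
  few <- assign_quartiles(make_candidates(c(0, 30, 60), c(0.1, 0.5, 0.9)))
  expect_equal(few$quartile, rep(4L, 3))

  expect_error(assign_quartiles(make_candidates(0, NaN)), "finite")
})

test_that("selection caps at ten and keeps the highest-scoring disjoint guides", {
  set.seed(2)
  # 30 disjoint high-score candidates + 90 low-score fillers so exactly the
  # 30 land in the top quartile
  starts <- c(seq(0, by = 23, length.out = 30), seq(3, by = 23, length.out = 90))
  scores <- c(runif(30, 0.8, 1), runif(90, 0, 0.7))
  cand <- assign_quartiles(make_candidates(starts, scores))
  expect_equal(sum(cand$quartile == 4), 30)

  res <- select_guides_for_transcript(cand, design_config())
  expect_equal(nrow(res$selected), 10)
  expect_equal(res$design_stage, "strict")
  expect_false(res$below_minimum)
  top10 <- sort(scores[1:30], decreasing = TRUE)[1:10]
  expect_equal(sort(res$selected$quality_score, decreasing = TRUE), top10)
})

test_that("relaxation stages trigger in order: quartile three, then overlap", {
  set.seed(3)
  # 3 disjoint Q4 + 4 disjoint Q3, all 7 mutually disjoint -> relaxed_q3
  cand <- make_candidates(seq(0, by = 30, length.out = 7),
                          c(0.9, 0.85, 0.8, 0.6, 0.55, 0.52, 0.51),
                          quartile = c(4, 4, 4, 3, 3, 3, 3))
  res <- select_guides_for_transcript(cand)
  expect_equal(nrow(res$selected), 7)
  expect_equal(res$design_stage, "relaxed_q3")
  expect_false(res$below_minimum)

  # only overlapping candidates: zero-overlap stages cannot reach five
  cand2 <- make_candidates(c(0, 13, 26, 39), c(0.9, 0.8, 0.7, 0.6),
                           quartile = c(4, 4, 3, 3))
  res2 <- select_guides_for_transcript(cand2)
  expect_equal(res2$design_stage, "relaxed_overlap")
  expect_equal(nrow(res2$selected), 4)
  expect_true(res2$below_minimum)
  ov <- outer(res2$selected$start, res2$selected$start, function(a, b)
    pmax(0, pmin(a + 23, b + 23) - pmax(a, b)))
  diag(ov) <- 0
  expect_true(all(ov <= 10))

  single <- select_guides_for_transcript(
    make_candidates(0, 0.4, quartile = 4))
  expect_equal(nrow(single$selected), 1)
  expect_true(single$below_minimum)
})

# an explicit, independent walk of the staged greedy used as oracle
reference_selection <- function(cand, cfg = design_config()) {
  pick <- function(pool, max_ov) {
    pool <- pool[order(-pool$quality_score, pool$start, pool$target_site_seq), ]
    chosen <- pool[0, ]
    for (i in seq_len(nrow(pool))) {
      if (nrow(chosen) >= cfg$target_per_transcript) break
      ovs <- if (nrow(chosen) == 0) 0 else
        max(pmax(0, pmin(pool$start[i] + cfg$guide_length,
                         chosen$start + cfg$guide_length) -
                     pmax(pool$start[i], chosen$start)))
      if (ovs <= max_ov) chosen <- rbind(chosen, pool[i, ])
    }
    chosen
  }
  s <- pick(cand[cand$quartile == 4, ], 0)
  if (nrow(s) >= cfg$min_guides) return(list(sel = s, stage = "strict"))
  s <- pick(cand[cand$quartile >= cfg$relax_quartile_min, ], 0)
  if (nrow(s) >= cfg$min_guides) return(list(sel = s, stage = "relaxed_q3"))
  list(sel = pick(cand[cand$quartile >= cfg$relax_quartile_min, ],
                  cfg$relax_overlap_max_nt),
       stage = "relaxed_overlap")
}

test_that("selection matches an independent staged-greedy oracle on random instances", {
  for (trial in 1:50) {
    set.seed(100 + trial)
    n <- sample(1:15, 1)
    cand <- make_candidates(sample(0:200, n), runif(n), quartile = sample(1:4, n, TRUE))
    got <- select_guides_for_transcript(cand)
    want <- reference_selection(cand)
    if (nrow(want$sel) == 0) {
      expect_equal(nrow(got$selected), 0)
    } else {
      expect_equal(got$selected$start, want$sel$start)
      expect_equal(got$design_stage, want$stage)
    }
    # permutation invariance: shuffled input gives identical output
    shuffled <- cand[sample(nrow(cand)), ]
    got2 <- select_guides_for_transcript(shuffled)
    expect_equal(got2$selected$start, got$selected$start)
  }
})

test_that("adding a dominated overlapping candidate never changes the selection", {
  # within one quartile pool, a lower-scoring candidate overlapping a selected
  # guide is considered last in every stage and rejected in all of them
  for (trial in 1:20) {
    set.seed(300 + trial)
    n <- sample(5:12, 1)
    cand <- make_candidates(sample(seq(0, 300, 5), n), runif(n, 0.3, 1),
                            quartile = rep(4, n))
    base <- select_guides_for_transcript(cand)
    if (nrow(base$selected) == 0) next
    extra <- make_candidates(base$selected$start[1] + 3,
                             min(base$selected$quality_score) - 0.1,
                             quartile = 4)
    more <- select_guides_for_transcript(rbind(cand, extra))
    expect_equal(more$selected$start, base$selected$start)
  }
})

test_that("library assembly dedups spacers and caps records per transcript", {
  set.seed(4)
  # same gene, two transcripts, same spacer -> one record
  spacer <- rand_dna(23)
  cand <- rbind(
    make_candidates(0, 0.9, transcript = "T1", gene = "G1"),
    make_candidates(5, 0.8, transcript = "T2", gene = "G1")
  )
  cand$target_site_seq <- spacer
  lib <- design_library(cand)
  expect_equal(nrow(lib), 1)
  expect_equal(lib$crRNA_id, "G1_1")

  # same spacer in two genes -> dropped entirely
  cand2 <- rbind(
    make_candidates(0, 0.9, transcript = "T1", gene = "G1"),
    make_candidates(5, 0.8, transcript = "T2", gene = "G2")
  )
  cand2$target_site_seq <- spacer
  expect_equal(nrow(design_library(cand2)), 0)

  # flanks and orientation switch
  c3 <- make_candidates(0, 0.9)
  cfg <- design_config(flank5 = "AAAC", flank3 = "GTTT")
  lib3 <- design_library(c3, config = cfg)
  expect_equal(lib3$oligo_seq, paste0("AAAC", lib3$spacer_seq, "GTTT"))
  librc <- design_library(c3, config = design_config(spacer_as = "reverse_complement"))
  expect_equal(librc$spacer_seq, rc(c3$target_site_seq))

  # control flagging
  libc <- design_library(c3, controls = "G1")
  expect_true(all(libc$is_control))
})

test_that("a 200-gene simulated candidate set yields exactly ten records per gene", {
  tx <- simulate_transcriptome(200, c(900, 1100), seed = 21)
  cand <- simulate_guide_scores(tx$transcripts, seed = 22)
  lib <- design_library(cand)
  expect_equal(nrow(lib), 2000)
  expect_true(all(table(lib$gene_id) == 10))
  expect_equal(anyDuplicated(lib$crRNA_id), 0L)
})

test_that("library tables round-trip through TSV with literal booleans", {
  tx <- simulate_transcriptome(3, c(300, 400), seed = 5)
  cand <- simulate_guide_scores(tx$transcripts, seed = 6)
  lib <- design_library(cand, controls = "G0002")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library_table(lib, path)
  expect_identical(as.data.frame(read_library_table(path)), as.data.frame(lib))
  raw <- readLines(path)
  expect_true(any(grepl("\ttrue\t", raw)) && any(grepl("\tfalse\t", raw)))
  expect_error(write_library_table(lib[0, ], path), "non-empty")
})
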