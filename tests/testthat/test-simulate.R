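test_that("transcriptome generation is deterministic, sized, and collision-free", {
  a <- simulate_transcriptome(5, c(200, 400), seed = 1)
  b <- simulate_transcriptome(5, c(200, 400), seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$transcripts), 5)
  expect_equal(nrow(a$intervals), 5)
  expect_true(all(a$transcripts$length >= 200 & a$transcripts$length <= 400))
  expect_equal(a$intervals$start, rep(0L, 5))
  expect_equal(a$intervals$end, a$transcripts$length)

  one <- simulate_transcriptome(1, c(100, 100), seed = 7)
  expect_equal(nchar(one$transcripts$sequence), 100)

  many <- simulate_transcriptome(50, c(500, 2000), seed = 3)
  expect_equal(anyDuplicated(many$transcripts$sequence), 0L)

  expect_error(simulate_transcriptome(3, c(400, 200)), "length_range")
  expect_error(simulate_transcriptome(3, c(50, 80)), "length_range")
})

test_that("guide scoring emits one uniform-scored candidate per position", {
  tx <- tibble::tibble(transcript_id = "T1", gene_id = "G1",
                       sequence = rand_dna(123))
  cand <- simulate_guide_scores(tx, guide_length = 23, seed = 2)
  expect_equal(nrow(cand), 101)
  expect_equal(cand$start, 0:100)
  expect_equal(cand$target_site_seq,
               substring(tx$sequence, 1:101, 23:123))

  expect_identical(cand, simulate_guide_scores(tx, guide_length = 23, seed = 2))

  big <- simulate_transcriptome(100, c(150, 160), seed = 9)
  scores <- simulate_guide_scores(big$transcripts, seed = 10)$quality_score
  expect_gt(length(scores), 1e4)
  expect_true(all(abs(quantile(scores, c(0.25, 0.5, 0.75)) - c(0.25, 0.5, 0.75)) < 0.02))

  short <- tibble::tibble(transcript_id = c("T1", "T2"), gene_id = c("G1", "G2"),
                          sequence = c(rand_dna(10), rand_dna(60)))
  expect_warning(out <- simulate_guide_scores(short, seed = 1), "skipped")
  expect_true(all(out$transcript_id == "T2"))
})

test_that("screen counts close to depth and truth is self-consistent", {
  p <- screen_sim_params(n_genes = 50, depth = 5e4, frac_positive = 0.1,
                         frac_negative = 0.1, seed = 3)
  sim <- simulate_screen(p)
  m <- as.matrix(sim$counts[, c(base_samples(), final_samples())])
  expect_true(all(colSums(m) == p$depth))
  expect_true(all(m >= 0))

  # identical draws under the same seed
  sim2 <- simulate_screen(p)
  expect_identical(sim, sim2)

  tg <- dplyr::inner_join(sim$truth$guides, sim$truth$genes, by = "gene_id")
  expect_equal(tg$realized_lfc, tg$efficacy * tg$delta)
  expect_true(all(tg$delta[tg$class == "null"] == 0))
  expect_true(all(abs(tg$realized_lfc) <= abs(tg$delta) + 1e-12))
})

test_that("null screens are flat after depth matching", {
  p <- screen_sim_params(n_genes = 200, depth = 2e5, seed = 4)
  sim <- simulate_screen(p)
  b <- rowMeans(as.matrix(sim$counts[, base_samples()]))
  f <- rowMeans(as.matrix(sim$counts[, final_samples()]))
  expect_lt(mean(abs(log2((f + 1) / (b + 1)))), 0.1)
})

test_that("positive-gene guides track efficacy times gene effect", {
  p <- screen_sim_params(n_genes = 200, coverage = 1000, depth = 1e6,
                         frac_positive = 0.05, effect_size = 2, seed = 11)
  sim <- simulate_screen(p)
  tg <- dplyr::inner_join(sim$truth$guides, sim$truth$genes, by = "gene_id")
  sel <- tg$class == "positive" & tg$efficacy > 0.8
  expect_gt(sum(sel), 20)
  b <- rowMeans(as.matrix(sim$counts[, base_samples()]))
  f <- rowMeans(as.matrix(sim$counts[, final_samples()]))
  lfc <- log2((f + 1) / (b + 1))
  expect_lt(abs(mean(lfc[sel]) - mean(tg$efficacy[sel] * 2)), 0.3)
})

test_that("decay series follow the exponential model exactly when noiseless", {
  s <- simulate_decay(decay_sim_params(noise_sd = 0))
  prot <- s[s$allele == "protective", ]
  expect_equal(round(prot$rel_abundance, 3), c(1, 0.828, 0.777, 0.604, 0.469))

  at11 <- simulate_decay(decay_sim_params(half_life_hours = c(x = 11),
                                          timepoints = c(0, 11), noise_sd = 0))
  expect_equal(at11$rel_abundance[2], 0.5)

  # the faster-decaying allele is strictly lower at every t > 0
  risk <- s[s$allele == "risk", ]
  expect_true(all(risk$rel_abundance[-1] < prot$rel_abundance[-1]))

  noisy <- decay_sim_params(noise_sd = 0.1, seed = 5)
  expect_identical(simulate_decay(noisy), simulate_decay(noisy))
})

test_that("fastq emission inverts exactly through count_reads", {
  lib <- tibble::tibble(
    crRNA_id = c("g1", "g2", "g3"),
    spacer_seq = vapply(1:3, function(i) rand_dna(23), character(1))
  )
  fq <- withr::local_tempfile(fileext = ".fastq")
  counts_in <- tibble::tibble(crRNA_id = c("g1", "g2"), count = c(3, 0))
  simulate_fastq(counts_in, lib, fq, flank5 = "GTGGAA", flank3 = "TTTTT", seed = 1)
  lines <- readLines(fq)
  expect_length(lines, 12)
  expect_true(all(grepl(lib$spacer_seq[1], lines[seq(2, 12, 4)], fixed = TRUE)))

  out <- count_reads(fq, lib, flank5 = "GTGGAA")
  expect_equal(out$counts$count, c(3, 0, 0))
  expect_equal(out$match_rate, 1)

  # larger random round trip, conservation of reads
  set.seed(2)
  counts_big <- tibble::tibble(crRNA_id = lib$crRNA_id, count = rpois(3, 40))
  simulate_fastq(counts_big, lib, fq, flank5 = "GTGGAA", flank3 = "TT", seed = 9)
  out2 <- count_reads(fq, lib, flank5 = "GTGGAA")
  expect_equal(out2$counts$count, counts_big$count)
  expect_equal(out2$total_reads, sum(counts_big$count))

  expect_error(
    simulate_fastq(tibble::tibble(crRNA_id = "nope", count = 1), lib, fq,
                   flank5 = "A", flank3 = "T"),
    "absent"
  )
})

test_that("pulldown simulation is deterministic with recoverable truth", {
  a <- simulate_pulldown(50, 5, enrich_log2fc = 3, noise_sd = 0.3, seed = 1)
  expect_identical(a, simulate_pulldown(50, 5, enrich_log2fc = 3, noise_sd = 0.3, seed = 1))
  expect_true(all(a$n_peptides[a$is_enriched] >= 5))

  # strongly enriched proteins pass the published filter
  res <- rank_pulldown(a)
  expect_true(all(res$passes_filters[match(a$protein_id[a$is_enriched], res$protein_id)]))

  # an all-null table passes (essentially) never under the joint filter
  null <- simulate_pulldown(200, 0, noise_sd = 0.5, seed = 2)
  expect_equal(sum(rank_pulldown(null)$passes_filters), 0)
})

test_that("library manifest reproduces the requested bookkeeping exactly", {
  m <- simulate_library_manifest(n_target_genes = 40, n_control_genes = 2,
                                 n_total = 408, seed = 3)
  expect_equal(nrow(m), 408)
  expect_equal(dplyr::n_distinct(m$gene_id[!m$is_control]), 40)
  expect_equal(dplyr::n_distinct(m$gene_id[m$is_control]), 2)
  sizes <- table(m$gene_id)
  expect_true(all(sizes >= 2 & sizes <= 10))
  expect_equal(anyDuplicated(m$spacer_seq), 0L)
})
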