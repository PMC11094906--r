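# small pure-R enumerator used to validate the exported brute-force oracle
r_enumerate_hits <- function(library, references, annotation,
                             max_mm = 2, min_cov = 0.9, both = FALSE) {
  rows <- list()
  for (gi in seq_len(nrow(library))) {
    guide <- library$spacer_seq[gi]
    L <- nchar(guide)
    lmin <- as.integer(ceiling(min_cov * L - 1e-9))
    for (strand in if (both) c("+", "-") else "+") {
      g <- strsplit(if (strand == "+") guide else rc(guide), "")[[1]]
      for (ref_id in names(references)) {
        r <- strsplit(references[[ref_id]], "")[[1]]
        for (len in lmin:L) {
          for (o in 0:(L - len)) {
            if (length(r) < len) next
            for (start in 0:(length(r) - len)) {
              mm <- sum(g[(o + 1):(o + len)] != r[(start + 1):(start + len)])
              if (mm > max_mm) next
              iv <- annotation[annotation$gene_id == library$gene_id[gi] &
                                 annotation$ref_id == ref_id, , drop = FALSE]
              if (nrow(iv) > 0 &&
                  any(iv$start < start + len & iv$end > start)) next
              goff <- if (strand == "+") o else L - o - len
              rows[[length(rows) + 1]] <- data.frame(
                crRNA_id = library$crRNA_id[gi], ref_id = ref_id,
                strand = strand, ref_start = start, guide_offset = goff,
                aligned_length = len, mismatches = mm)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(crRNA_id = character(0), ref_id = character(0),
                      strand = character(0), ref_start = integer(0),
                      guide_offset = integer(0), aligned_length = integer(0),
                      mismatches = integer(0)))
  }
  h <- do.call(rbind, rows)
  h$anchor <- ifelse(h$strand == "+", h$ref_start, h$ref_start + h$aligned_length)
  h <- h[order(h$crRNA_id, h$ref_id, h$anchor, h$strand,
               -h$aligned_length, h$mismatches, h$guide_offset), ]
  h <- h[!duplicated(h[, c("crRNA_id", "ref_id", "anchor", "strand")]), ]
  h$anchor <- NULL
  h <- h[order(h$crRNA_id, h$ref_id, h$ref_start, h$strand), ]
  rownames(h) <- NULL
  h
}

self_lib <- function(guide, tx) {
  list(
    library = tibble::tibble(crRNA_id = "g1", gene_id = "GENE1", spacer_seq = guide),
    annotation = tibble::tibble(ref_id = "T1", start = 0L, end = nchar(tx),
                                gene_id = "GENE1")
  )
}

test_that("exact and two-mismatch copies are found; spread three-mismatch copies are not", {
  set.seed(11)
  guide <- rand_dna(23)
  tx <- paste0(rand_dna(40), guide, rand_dna(40))
  sl <- self_lib(guide, tx)

  exact <- c(T1 = tx, G1 = paste0(rand_dna(80), guide, rand_dna(80)))
  h <- scan_offtargets(sl$library, exact, sl$annotation)
  full <- h[h$aligned_length == 23, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$mismatches, 0L)
  expect_equal(full$coverage, 1)
  expect_equal(full$ref_start, 80L)

  # two mismatches anywhere: still a hit at full length
  mm2 <- mutate_seq(guide, 0, positions = c(1, 23))
  h2 <- scan_offtargets(sl$library, c(T1 = tx, G1 = paste0(rand_dna(50), mm2, rand_dna(50))),
                        sl$annotation)
  expect_true(any(h2$aligned_length == 23 & h2$mismatches == 2))

  # three mismatches confined to positions 3..21 so every >= 21-nt window
  # carries all three: no qualifying placement remains
  mm3 <- mutate_seq(guide, 0, positions = c(3, 12, 18))
  h3 <- scan_offtargets(sl$library, c(T1 = tx, G1 = paste0(rand_dna(50), mm3, rand_dna(50))),
                        sl$annotation)
  expect_equal(nrow(h3), 0)
})

test_that("partial placements respect the coverage floor and collapse to maximal length", {
  set.seed(12)
  guide <- rand_dna(23)
  tx <- paste0(rand_dna(40), guide, rand_dna(40))
  sl <- self_lib(guide, tx)
  core21 <- substr(guide, 2, 22)

  # the 21-nt core alone (nothing to extend into) -> 21/23 = 0.913 coverage
  h <- scan_offtargets(sl$library, c(T1 = tx, G1 = core21), sl$annotation)
  expect_equal(nrow(h), 1)
  expect_equal(h$aligned_length, 21L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$guide_offset, 1L)
  expect_equal(h$coverage, 21 / 23, tolerance = 1e-12)

  # embedded with mismatching flanks, extension to full length costs exactly
  # the two flank mismatches and wins the per-locus collapse
  l <- mutate_seq(substr(guide, 1, 1), 1)
  r <- mutate_seq(substr(guide, 23, 23), 1)
  emb <- c(T1 = tx, G1 = paste0(rand_dna(30), l, core21, r, rand_dna(30)))
  h2 <- scan_offtargets(sl$library, emb, sl$annotation)
  expect_true(any(h2$aligned_length == 23 & h2$mismatches == 2 & h2$ref_start == 30))

  # a 20-nt exact copy is below the coverage floor
  h3 <- scan_offtargets(sl$library, c(T1 = tx, G1 = substr(guide, 2, 21)), sl$annotation)
  expect_equal(nrow(h3), 0)
})

test_that("strand handling and self-exclusion follow the contract", {
  set.seed(13)
  guide <- rand_dna(23)
  tx <- paste0(rand_dna(40), guide, rand_dna(40))
  sl <- self_lib(guide, tx)
  refs <- c(T1 = tx, G1 = paste0(rand_dna(70), rc(guide), rand_dna(70)))

  minus <- scan_offtargets(sl$library, refs, sl$annotation,
                           scan_config(scan_both_strands = TRUE))
  expect_true(all(minus$strand == "-"))
  expect_true(any(minus$aligned_length == 23 & minus$ref_start == 70))
  # transcriptome mode ignores the antisense copy
  expect_equal(nrow(scan_offtargets(sl$library, refs, sl$annotation)), 0)

  # a guide whose only match is its own gene yields nothing
  own_only <- scan_offtargets(sl$library, c(T1 = tx), sl$annotation,
                              scan_config(scan_both_strands = TRUE))
  expect_equal(nrow(own_only), 0)
})

test_that("reverse-complementing the reference flips strands and mirrors coordinates", {
  inst <- make_scan_instance(77, n_guides = 20, ref_len = 8000, tx_len = 1000,
                             n_plants = 10)
  cfg <- scan_config(scan_both_strands = TRUE)
  fwd <- scan_offtargets(inst$library, inst$references, inst$annotation, cfg)
  flipped_refs <- vapply(inst$references, rc, character(1))
  lens <- nchar(inst$references)
  ann_flip <- inst$annotation
  ann_flip$start <- lens[ann_flip$ref_id] - inst$annotation$end
  ann_flip$end <- lens[ann_flip$ref_id] - inst$annotation$start
  rev <- scan_offtargets(inst$library, flipped_refs, ann_flip, cfg)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- fwd
  mirrored$strand <- ifelse(fwd$strand == "+", "-", "+")
  mirrored$ref_start <- lens[fwd$ref_id] - (fwd$ref_start + fwd$aligned_length)
  key <- function(d) paste(d$crRNA_id, d$ref_id, d$strand, d$ref_start,
                           d$aligned_length, d$mismatches)
  expect_setequal(key(mirrored), key(rev))
})

test_that("relaxing mismatch or coverage thresholds never removes a hit", {
  inst <- make_scan_instance(78, n_guides = 30, ref_len = 10000, tx_len = 1500,
                             n_plants = 15)
  # compare loci by their strand-aware anchor: a longer qualifying placement
  # at the same locus legitimately shifts ref_start on the minus strand
  key <- function(d) paste(d$crRNA_id, d$ref_id, d$strand,
                           ifelse(d$strand == "+", d$ref_start,
                                  d$ref_start + d$aligned_length))
  base <- scan_offtargets(inst$library, inst$references, inst$annotation,
                          scan_config(scan_both_strands = TRUE))
  more_mm <- scan_offtargets(inst$library, inst$references, inst$annotation,
                             scan_config(max_mismatches = 3, scan_both_strands = TRUE))
  less_cov <- scan_offtargets(inst$library, inst$references, inst$annotation,
                              scan_config(min_coverage = 0.8, scan_both_strands = TRUE))
  expect_true(all(key(base) %in% key(more_mm)))
  expect_true(all(key(base) %in% key(less_cov)))
})

test_that("the exported brute-force oracle matches a pure-R enumeration on small instances", {
  for (trial in 1:10) {
    set.seed(500 + trial)
    tx <- rand_dna(200)
    lib <- tibble::tibble(
      crRNA_id = sprintf("g%d", 1:5), gene_id = "GENEX",
      spacer_seq = vapply(1:5, function(i) {
        s <- sample(170, 1); substr(tx, s, s + 22)
      }, character(1)))
    lib <- lib[!duplicated(lib$spacer_seq), ]
    other <- rand_dna(250)
    m <- mutate_seq(lib$spacer_seq[1], sample(0:3, 1))
    if (trial %% 2 == 0) m <- rc(m)
    substr(other, 100, 122) <- m
    refs <- c(TX = tx, GG = other)
    ann <- tibble::tibble(ref_id = "TX", start = 0L, end = 200L, gene_id = "GENEX")
    got <- brute_force_scan(lib, refs, ann, scan_config(scan_both_strands = TRUE))
    want <- r_enumerate_hits(lib, refs, ann, both = TRUE)
    expect_equal(as.data.frame(got[, names(want)]), want)
  }
})

test_that("hit-bearing guides are removed and the rest of the library is untouched", {
  set.seed(14)
  guides <- vapply(1:5, function(i) rand_dna(23), character(1))
  lib <- tibble::tibble(crRNA_id = paste0("g", 1:5), gene_id = paste0("G", 1:5),
                        spacer_seq = guides)
  tx <- paste0(paste(guides, collapse = ""), rand_dna(20))
  ann <- tibble::tibble(ref_id = "T1", start = (0:4) * 23L, end = (1:5) * 23L,
                        gene_id = paste0("G", 1:5))
  # plant copies of g2 and g4 outside their own genes
  refs <- c(T1 = tx, G1 = paste0(rand_dna(30), guides[2], rand_dna(30),
                                 guides[4], rand_dna(30)))
  hits <- scan_offtargets(lib, refs, ann)
  res <- filter_library(lib, hits)
  expect_equal(res$retained$crRNA_id, c("g1", "g3", "g5"))
  expect_setequal(res$removed$crRNA_id, c("g2", "g4"))
  expect_true(all(res$removed$worst_mismatches == 0))

  # no hits: identity
  none <- filter_library(lib, hits[0, ])
  expect_identical(none$retained, lib)

  # all removed: empty library plus a warning
  all_hits <- scan_offtargets(lib, c(T1 = tx, G1 = paste0(paste(guides, collapse = "A"))), ann)
  expect_warning(allres <- filter_library(lib, all_hits), "all guides")
  expect_equal(nrow(allres$retained), 0)

  bad <- hits
  bad$crRNA_id[1] <- "mystery"
  expect_error(filter_library(lib, bad), "not in the library")
})
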