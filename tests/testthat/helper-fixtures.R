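# in-code fixtures shared across the suite

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mutate_seq <- function(s, k, positions = NULL) {
  v <- strsplit(s, "")[[1]]
  pos <- positions %||% (if (k > 0) sample(length(v), k) else integer(0))
  for (i in pos) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  paste(v, collapse = "")
}

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random off-target scan instance: guides drawn from an annotated
# "transcript" reference (so each has an excluded self-match) and mutated
# copies (0-4 mismatches, both strands) planted into a larger reference
make_scan_instance <- function(seed, n_guides = 100, ref_len = 50000,
                               tx_len = 3000, n_plants = 20) {
  withr::with_seed(seed, {
    txs <- rand_dna(tx_len)
    ref_g <- rand_dna(ref_len - tx_len)
    lib <- tibble::tibble(
      crRNA_id = sprintf("g%03d", seq_len(n_guides)),
      gene_id = "GENEX",
      spacer_seq = vapply(seq_len(n_guides), function(i) {
        s <- sample(tx_len - 30, 1)
        substr(txs, s, s + 22)
      }, character(1))
    )
    lib <- lib[!duplicated(lib$spacer_seq), , drop = FALSE]
    for (i in seq_len(n_plants)) {
      m <- mutate_seq(lib$spacer_seq[sample(nrow(lib), 1)], sample(0:4, 1))
      if (runif(1) < 0.5) m <- rc(m)
      pos <- sample(nchar(ref_g) - 30, 1)
      substr(ref_g, pos, pos + 22) <- m
    }
    list(
      library = lib,
      references = c(TX = txs, GG = ref_g),
      annotation = tibble::tibble(ref_id = "TX", start = 0L, end = tx_len,
                                  gene_id = "GENEX")
    )
  })
}

# candidate table builder for library-design tests
make_candidates <- function(starts, scores, quartile = NULL, transcript = "T1",
                            gene = "G1", guide_length = 23) {
  out <- tibble::tibble(
    transcript_id = transcript,
    gene_id = gene,
    start = as.integer(starts),
    target_site_seq = vapply(seq_along(starts), function(i) rand_dna(guide_length),
                             character(1)),
    quality_score = scores
  )
  if (!is.null(quartile)) out$quartile <- as.integer(quartile)
  out
}

base_samples <- function(n = 3) paste0("baseline_", seq_len(n))
final_samples <- function(n = 3) paste0("final_", seq_len(n))
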