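# synthetic-data module: every input the pipeline consumes can be generated
# here, with stated distributions and full seed determinism

random_dna <- function(n, lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a toy transcriptome
#'
#' Generates uniformly random ACGT transcripts with one gene per transcript
#' and a matching interval table (0-based half-open, one interval covering
#' each transcript's full extent). Duplicate sequences are regenerated so the
#' returned transcripts are pairwise distinct.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Length bounds in nucleotides, `c(min, max)`, both
#'   >= 100.
#' @param seed Integer seed; output is a deterministic function of the
#'   arguments.
#' @return A list with `transcripts` (tibble: transcript_id, gene_id,
#'   sequence, length) and `intervals` (tibble: ref_id, start, end, gene_id).
#' @export
#' @examples
#' tx <- simulate_transcriptome(5, c(200, 400), seed = 1)
#' tx$transcripts
simulate_transcriptome <- function(n_transcripts, length_range = c(200L, 400L), seed = 1L) {
  assert_count(n_transcripts, "n_transcripts")
  assert_that(is.numeric(length_range) && length(length_range) == 2L &&
                all(is.finite(length_range)) && length_range[1] <= length_range[2] &&
                length_range[1] >= 100,
              "`length_range` must be c(min, max) with 100 <= min <= max")
  assert_seed(seed)
  withr::with_seed(seed, {
    len_pool <- seq(length_range[1], length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n_transcripts, replace = TRUE)]
    seqs <- random_dna(n_transcripts, lens)
    for (iter in 1:100) {
      dup <- duplicated(seqs)
      if (!any(dup)) break
      seqs[dup] <- random_dna(sum(dup), lens[dup])
    }
    assert_that(!any(duplicated(seqs)), "failed to generate distinct transcript sequences")
    transcripts <- tibble(
      transcript_id = sprintf("T%04d", seq_len(n_transcripts)),
      gene_id = sprintf("G%04d", seq_len(n_transcripts)),
      sequence = seqs,
      length = nchar(seqs)
    )
    intervals <- tibble(
      ref_id = transcripts$transcript_id,
      start = 0L,
      end = transcripts$length,
      gene_id = transcripts$gene_id
    )
    list(transcripts = transcripts, intervals = intervals)
  })
}

#' Simulate scored guide candidates
#'
#' Emits one candidate per transcript position (0-based starts `0 .. len - L`)
#' with quality scores drawn i.i.d. uniform(0, 1), standing in for an
#' upstream guide-scoring model. Transcripts shorter than the guide are
#' skipped with a warning.
#'
#' @param transcripts Tibble with `transcript_id`, `gene_id`, `sequence`
#'   (as from [simulate_transcriptome()]).
#' @param guide_length Spacer length in nucleotides.
#' @param seed Integer seed.
#' @return Candidate tibble: transcript_id, gene_id, start, target_site_seq,
#'   quality_score.
#' @export
#' @examples
#' tx <- simulate_transcriptome(2, c(120, 150), seed = 1)
#' head(simulate_guide_scores(tx$transcripts, seed = 2))
simulate_guide_scores <- function(transcripts, guide_length = 23L, seed = 1L) {
  assert_columns(transcripts, c("transcript_id", "gene_id", "sequence"), "transcripts")
  assert_count(guide_length, "guide_length")
  assert_seed(seed)
  lens <- nchar(transcripts$sequence)
  drop <- lens < guide_length
  if (any(drop)) {
    warn(sprintf("%d transcript(s) shorter than the guide length were skipped", sum(drop)))
    transcripts <- transcripts[!drop, , drop = FALSE]
    lens <- lens[!drop]
  }
  assert_that(nrow(transcripts) > 0, "no transcript is at least the guide length")
  withr::with_seed(seed, {
    cand <- purrr::pmap_dfr(
      list(transcripts$transcript_id, transcripts$gene_id, transcripts$sequence, lens),
      function(tid, gid, seq, len) {
        starts <- 0:(len - guide_length)
        tibble(
          transcript_id = tid,
          gene_id = gid,
          start = starts,
          target_site_seq = substring(seq, starts + 1L, starts + guide_length)
        )
      }
    )
    cand$quality_score <- runif(nrow(cand))
    cand
  })
}

make_sim_library <- function(params) {
  gene_id <- rep(sprintf("G%04d", seq_len(params$n_genes)), each = params$guides_per_gene)
  tibble(
    crRNA_id = paste0(gene_id, "_", rep(seq_len(params$guides_per_gene), params$n_genes)),
    gene_id = gene_id,
    is_control = FALSE
  )
}

#' Simulate pooled-screen guide counts with ground truth
#'
#' Generative model: each guide i gets a baseline natural-log abundance
#' `a_i ~ Normal(0, sigma_lib^2)`; each non-control gene g is drawn positive,
#' negative or null with the configured fractions and assigned a signed total
#' log2 fold-change `delta_g` (+/- `effect_size`, 0 for null); each guide
#' draws a knockdown efficacy `u_i ~ Beta(efficacy_alpha, efficacy_beta)` so
#' its realized log2 fold-change is `u_i * delta_g`. Baseline samples draw
#' counts from Multinomial(depth, p) with `p ∝ exp(a_i)`; final samples use
#' `p ∝ exp(a_i) * 2^(u_i * delta_g)`. Replicates share the true abundances
#' and effects but draw sequencing counts independently.
#'
#' @param params A [screen_sim_params()] object.
#' @param library Optional library tibble (`crRNA_id`, `gene_id`, optionally
#'   `is_control`); when `NULL` a bare library with `params$n_genes *
#'   params$guides_per_gene` guides is created. Control guides are always
#'   null.
#' @return A list: `counts` (wide tibble: crRNA_id, gene_id, is_control, one
#'   column per sample), `samples` (tibble: sample_id, timepoint, replicate),
#'   and `truth` (list of `genes` and `guides` tibbles).
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_params(n_genes = 20, depth = 20000, seed = 1))
#' sim$counts[1:3, ]
simulate_screen <- function(params, library = NULL) {
  assert_that(inherits(params, "cas13_sim_params"), "`params` must come from screen_sim_params()")
  if (is.null(library)) library <- make_sim_library(params)
  assert_columns(library, c("crRNA_id", "gene_id"), "library")
  assert_that(nrow(library) >= 1, "`library` must be non-empty")
  assert_that(!anyDuplicated(library$crRNA_id), "crRNA_id values must be unique")
  if (!"is_control" %in% names(library)) library$is_control <- FALSE
  n_guides <- nrow(library)
  assert_that(params$depth >= n_guides, "`depth` must be at least the number of guides")

  withr::with_seed(params$seed, {
    genes <- unique(library$gene_id)
    target_genes <- unique(library$gene_id[!library$is_control])
    g <- length(target_genes)
    n_pos <- round(params$frac_positive * g)
    n_neg <- round(params$frac_negative * g)
    shuffled <- sample(target_genes)
    class <- setNames(rep("null", length(genes)), genes)
    if (n_pos > 0) class[shuffled[seq_len(n_pos)]] <- "positive"
    if (n_neg > 0) class[shuffled[n_pos + seq_len(n_neg)]] <- "negative"
    delta <- setNames(rep(0, length(genes)), genes)
    delta[class == "positive"] <- params$effect_size
    delta[class == "negative"] <- -params$effect_size

    a <- rnorm(n_guides, 0, params$sigma_lib)
    u <- rbeta(n_guides, params$efficacy_alpha, params$efficacy_beta)
    delta_guide <- delta[library$gene_id]
    lfc <- u * delta_guide

    p_base <- exp(a)
    p_base <- p_base / sum(p_base)
    p_final <- exp(a) * 2^lfc
    p_final <- p_final / sum(p_final)

    nrep <- params$n_replicates
    base_cols <- sprintf("baseline_%d", seq_len(nrep))
    final_cols <- sprintf("final_%d", seq_len(nrep))
    counts <- tibble(
      crRNA_id = library$crRNA_id,
      gene_id = library$gene_id,
      is_control = library$is_control
    )
    for (s in base_cols) counts[[s]] <- as.numeric(rmultinom(1, params$depth, p_base)[, 1])
    for (s in final_cols) counts[[s]] <- as.numeric(rmultinom(1, params$depth, p_final)[, 1])

    samples <- tibble(
      sample_id = c(base_cols, final_cols),
      timepoint = rep(c("baseline", "final"), each = nrep),
      replicate = rep(seq_len(nrep), 2L)
    )
    truth <- list(
      genes = tibble(gene_id = genes, class = unname(class), delta = unname(delta)),
      guides = tibble(
        crRNA_id = library$crRNA_id,
        gene_id = library$gene_id,
        efficacy = u,
        realized_lfc = unname(lfc)
      )
    )
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Write simulated screen reads as FASTQ
#'
#' Emits exactly `count` reads per guide, each read being
#' `flank5 + spacer + flank3` with a constant quality string (`I`), in a
#' seed-determined shuffled order. Inverts exactly through [count_reads()].
#'
#' @param counts Tibble with `crRNA_id` and `count` columns (or a named
#'   integer vector).
#' @param library Library tibble with `crRNA_id` and `spacer_seq`.
#' @param path Output FASTQ path.
#' @param flank5,flank3 Non-empty constant flanks around the spacer.
#' @param seed Integer seed controlling the read order.
#' @return The output path, invisibly.
#' @export
simulate_fastq <- function(counts, library, path, flank5, flank3, seed = 1L) {
  if (!is.data.frame(counts)) {
    counts <- tibble(crRNA_id = names(counts), count = as.numeric(counts))
  }
  assert_columns(counts, c("crRNA_id", "count"), "counts")
  assert_columns(library, c("crRNA_id", "spacer_seq"), "library")
  assert_that(all(counts$count >= 0) && all(counts$count == round(counts$count)),
              "`count` values must be non-negative integers")
  assert_that(nzchar(flank5) && nzchar(flank3), "flanks must be non-empty")
  missing <- setdiff(counts$crRNA_id, library$crRNA_id)
  assert_that(length(missing) == 0,
              sprintf("guide(s) absent from library: %s",
                      paste(head(missing, 5), collapse = ", ")))
  assert_seed(seed)
  spacer <- setNames(library$spacer_seq, library$crRNA_id)
  ids <- rep(counts$crRNA_id, counts$count)
  withr::with_seed(seed, {
    if (length(ids) > 1) ids <- sample(ids)
  })
  seqs <- paste0(flank5, spacer[ids], flank3)
  qual <- strrep("I", nchar(seqs))
  lines <- character(4L * length(ids))
  if (length(ids) > 0) {
    idx <- seq_along(ids)
    lines[4 * idx - 3] <- sprintf("@read_%06d %s", idx, ids)
    lines[4 * idx - 2] <- seqs
    lines[4 * idx - 1] <- "+"
    lines[4 * idx] <- qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an exponential RNA decay time course
#'
#' Relative abundance follows `exp(-k t) * exp(eps)` with `k = ln(2) /
#' half-life` and `eps ~ Normal(0, noise_sd^2)`; with `noise_sd = 0` the
#' series is exact and starts at 1.
#'
#' @param params A [decay_sim_params()] object.
#' @return Tibble: allele, t_hours, rel_abundance.
#' @export
#' @examples
#' simulate_decay(decay_sim_params())
simulate_decay <- function(params = decay_sim_params()) {
  assert_that(inherits(params, "cas13_decay_params"), "`params` must come from decay_sim_params()")
  withr::with_seed(params$seed, {
    purrr::imap_dfr(params$half_life_hours, function(hl, allele) {
      k <- log(2) / hl
      eps <- if (params$noise_sd > 0) rnorm(length(params$timepoints), 0, params$noise_sd) else 0
      tibble(
        allele = allele,
        t_hours = params$timepoints,
        rel_abundance = exp(-k * params$timepoints + eps)
      )
    })
  })
}

#' Simulate an RNA pull-down enrichment table
#'
#' Per protein, `n_replicates` log2 abundance ratios over the control capture
#' are drawn Normal(mu, noise_sd^2) with `mu = enrich_log2fc` for the first
#' `n_enriched` proteins and 0 otherwise. Peptide counts are uniform on
#' 1..30, with enriched proteins forced to at least 5 so the truth is
#' recoverable by the published filter.
#'
#' @param n_proteins Total proteins.
#' @param n_enriched Number of truly enriched proteins (<= `n_proteins`).
#' @param enrich_log2fc True mean log2 fold-change of enriched proteins.
#' @param noise_sd Replicate noise standard deviation (log2 units).
#' @param n_replicates Biological replicates (default 5).
#' @param seed Integer seed.
#' @return Wide tibble: protein_id, is_enriched (truth), n_peptides,
#'   rep1..repN log2 ratios.
#' @export
#' @examples
#' simulate_pulldown(10, 2, seed = 1)
simulate_pulldown <- function(n_proteins, n_enriched, enrich_log2fc = 3,
                              noise_sd = 0.5, n_replicates = 5L, seed = 1L) {
  assert_count(n_proteins, "n_proteins")
  assert_count(n_enriched, "n_enriched", min = 0L)
  assert_that(n_enriched <= n_proteins, "`n_enriched` must be <= `n_proteins`")
  assert_number(enrich_log2fc, "enrich_log2fc")
  assert_number(noise_sd, "noise_sd", min = 0)
  assert_count(n_replicates, "n_replicates", min = 2L)
  assert_seed(seed)
  withr::with_seed(seed, {
    enriched <- seq_len(n_proteins) <= n_enriched
    mu <- ifelse(enriched, enrich_log2fc, 0)
    pep <- sample(1:30, n_proteins, replace = TRUE)
    pep[enriched] <- pmax(pep[enriched], 5L)
    ratios <- matrix(rnorm(n_proteins * n_replicates, rep(mu, n_replicates), noise_sd),
                     nrow = n_proteins)
    colnames(ratios) <- sprintf("rep%d", seq_len(n_replicates))
    dplyr::bind_cols(
      tibble(
        protein_id = sprintf("P%04d", seq_len(n_proteins)),
        is_enriched = enriched,
        n_peptides = pep
      ),
      as_tibble(ratios)
    )
  })
}

#' Synthetic full-scale library manifest
#'
#' Builds a synthetic crRNA library table with the bookkeeping shape of a
#' full-scale screen library: `n_target_genes` target genes plus
#' `n_control_genes` chromosome-Y negative-control genes, ten guides per gene
#' except for a small fraction of target genes that keep only 2-9 guides, so
#' that the table totals exactly `n_total` records. Spacer sequences are
#' random and the table is synthetic throughout; it exists so that
#' table-parsing and bookkeeping code can be exercised at realistic scale
#' without any external file.
#'
#' @param n_target_genes Number of non-control target genes.
#' @param n_control_genes Number of control genes (ten guides each).
#' @param n_total Total crRNA records in the manifest.
#' @param guides_per_gene Full per-gene guide count.
#' @param guide_length Spacer length.
#' @param seed Integer seed.
#' @return A library tibble with the [design_library()] column contract.
#' @export
#' @examples
#' m <- simulate_library_manifest(n_target_genes = 20, n_control_genes = 2, n_total = 210)
#' nrow(m)
simulate_library_manifest <- function(n_target_genes = 1864L,
                                      n_control_genes = 20L,
                                      n_total = 18248L,
                                      guides_per_gene = 10L,
                                      guide_length = 23L,
                                      seed = 1L) {
  assert_count(n_target_genes, "n_target_genes")
  assert_count(n_control_genes, "n_control_genes", min = 0L)
  assert_count(n_total, "n_total")
  assert_count(guides_per_gene, "guides_per_gene", min = 2L)
  assert_seed(seed)
  full_total <- (n_target_genes + n_control_genes) * guides_per_gene
  deficit <- full_total - n_total
  assert_that(deficit >= 0, "`n_total` exceeds genes * guides_per_gene")
  max_def <- guides_per_gene - 2L  # short genes keep at least two guides
  n_short <- if (deficit == 0) 0L else max(ceiling(deficit / max_def),
                                           round(0.05 * n_target_genes))
  assert_that(n_short <= n_target_genes, "deficit cannot be distributed")
  withr::with_seed(seed, {
    defs <- integer(0)
    if (n_short > 0) {
      base <- deficit %/% n_short
      rem <- deficit %% n_short
      defs <- rep(base, n_short) + c(rep(1L, rem), rep(0L, n_short - rem))
      assert_that(all(defs >= 1) && all(defs <= max_def),
                  "deficit cannot be distributed as 2-9 guide genes")
    }
    gene_ids <- sprintf("G%05d", seq_len(n_target_genes))
    n_guides <- setNames(rep(guides_per_gene, n_target_genes), gene_ids)
    short_genes <- sample(gene_ids, n_short)
    n_guides[short_genes] <- guides_per_gene - defs

    ctrl_ids <- if (n_control_genes > 0) sprintf("chrY_CTRL%03d", seq_len(n_control_genes)) else character(0)
    all_genes <- c(gene_ids, ctrl_ids)
    all_n <- c(n_guides, setNames(rep(guides_per_gene, n_control_genes), ctrl_ids))

    gene_col <- rep(all_genes, all_n)
    rank_col <- unlist(lapply(all_n, seq_len), use.names = FALSE)
    total <- length(gene_col)
    spacers <- random_dna(total, rep(guide_length, total))
    for (iter in 1:100) {
      dup <- duplicated(spacers)
      if (!any(dup)) break
      spacers[dup] <- random_dna(sum(dup), rep(guide_length, sum(dup)))
    }
    tibble(
      crRNA_id = paste0(gene_col, "_", rank_col),
      gene_id = gene_col,
      transcript_id = sub("^G", "T", gene_col),
      spacer_seq = spacers,
      oligo_seq = spacers,
      is_control = gene_col %in% ctrl_ids,
      design_stage = ifelse(rep(all_n, all_n) < guides_per_gene, "relaxed_overlap", "strict"),
      below_minimum = rep(all_n, all_n) < 5L
    )
  })
}
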