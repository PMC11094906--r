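#' Parameters for the pooled-screen count simulator
#'
#' Bundles and validates the generative-model parameters used by
#' [simulate_screen()]. The defaults describe a desk-scale screen: 200 genes
#' with ten guides each, three biological replicates, and a sequencing depth
#' of 2e5 reads per sample (a 1:100 scale-down of the 20 million reads per
#' replicate used at full screen scale, keeping ~100 reads per guide).
#' `coverage` records the design's cells-per-guide at transduction (1000 at
#' full scale); the count model itself is purely multinomial, so `coverage`
#' is carried as metadata and validated but adds no stochastic layer.
#'
#' @param n_genes Number of target genes.
#' @param guides_per_gene Guides designed per gene.
#' @param n_replicates Biological replicates per timepoint.
#' @param coverage Cells per guide at transduction (metadata).
#' @param depth Total reads per sample; must be at least the guide count.
#' @param sigma_lib Standard deviation of natural-log baseline guide
#'   abundance (library cloning unevenness).
#' @param frac_positive,frac_negative Fractions of genes whose knockdown
#'   truly increases / decreases proliferation.
#' @param effect_size Gene-level total log2 fold-change magnitude for
#'   non-null genes.
#' @param efficacy_alpha,efficacy_beta Shape parameters of the Beta
#'   distribution of per-guide knockdown efficacy.
#' @param seed Integer seed; every draw in [simulate_screen()] is a
#'   deterministic function of the parameters and this seed.
#' @return A validated `cas13_sim_params` list.
#' @export
#' @examples
#' p <- screen_sim_params(n_genes = 20, depth = 20000, seed = 1)
screen_sim_params <- function(n_genes = 200L,
                              guides_per_gene = 10L,
                              n_replicates = 3L,
                              coverage = 1000L,
                              depth = 2e5,
                              sigma_lib = 0.15,
                              frac_positive = 0,
                              frac_negative = 0,
                              effect_size = 2,
                              efficacy_alpha = 5,
                              efficacy_beta = 2,
                              seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(guides_per_gene, "guides_per_gene")
  assert_count(n_replicates, "n_replicates")
  assert_count(coverage, "coverage")
  assert_count(depth, "depth")
  assert_number(sigma_lib, "sigma_lib", min = 0)
  assert_number(frac_positive, "frac_positive", min = 0, max = 1)
  assert_number(frac_negative, "frac_negative", min = 0, max = 1)
  assert_that(frac_positive + frac_negative <= 1,
              "`frac_positive` + `frac_negative` must be <= 1")
  assert_number(effect_size, "effect_size", min = 0)
  assert_number(efficacy_alpha, "efficacy_alpha", min = 0, strict_min = TRUE)
  assert_number(efficacy_beta, "efficacy_beta", min = 0, strict_min = TRUE)
  assert_seed(seed)
  assert_that(depth >= n_genes * guides_per_gene,
              "`depth` must be at least n_genes * guides_per_gene")
  structure(
    list(
      n_genes = as.integer(n_genes),
      guides_per_gene = as.integer(guides_per_gene),
      n_replicates = as.integer(n_replicates),
      coverage = as.integer(coverage),
      depth = depth,
      sigma_lib = sigma_lib,
      frac_positive = frac_positive,
      frac_negative = frac_negative,
      effect_size = effect_size,
      efficacy_alpha = efficacy_alpha,
      efficacy_beta = efficacy_beta,
      seed = as.integer(seed)
    ),
    class = "cas13_sim_params"
  )
}

#' Parameters for the RNA decay simulator
#'
#' Defaults match an allele-specific transcription-shutoff experiment:
#' harvests at 0, 3, 4, 8 and 12 hours after actinomycin D, with the
#' protective-allele transcript decaying at an 11 h half-life and the
#' risk-allele transcript at 6 h.
#'
#' @param half_life_hours Named numeric vector of half-lives (> 0), one per
#'   allele label.
#' @param timepoints Harvest times in hours; non-negative, strictly
#'   increasing, starting at 0.
#' @param noise_sd Standard deviation of multiplicative log-normal noise.
#' @param seed Integer seed.
#' @return A validated `cas13_decay_params` list.
#' @export
#' @examples
#' decay_sim_params(noise_sd = 0.05, seed = 3)
decay_sim_params <- function(half_life_hours = c(protective = 11, risk = 6),
                             timepoints = c(0, 3, 4, 8, 12),
                             noise_sd = 0,
                             seed = 1L) {
  assert_that(is.numeric(half_life_hours) && length(half_life_hours) >= 1 &&
                all(is.finite(half_life_hours)) && all(half_life_hours > 0),
              "`half_life_hours` must be positive numbers")
  assert_that(!is.null(names(half_life_hours)) && !any(names(half_life_hours) == ""),
              "`half_life_hours` must be named by allele")
  assert_that(is.numeric(timepoints) && length(timepoints) >= 2 &&
                all(timepoints >= 0) && !is.unsorted(timepoints, strictly = TRUE) &&
                timepoints[1] == 0,
              "`timepoints` must be non-negative, strictly increasing, and include 0")
  assert_number(noise_sd, "noise_sd", min = 0)
  assert_seed(seed)
  structure(
    list(half_life_hours = half_life_hours, timepoints = timepoints,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cas13_decay_params"
  )
}

#' Configuration for crRNA library design
#'
#' Encodes the staged selection rules: aim for `target_per_transcript`
#' non-overlapping top-quartile guides; if fewer than `min_guides` survive,
#' first admit guides down to quartile `relax_quartile_min`, then tolerate
#' pairwise overlaps up to `relax_overlap_max_nt` nucleotides, in this order.
#'
#' @param target_per_transcript Maximum guides selected per transcript.
#' @param min_guides Minimum acceptable guides before relaxation stops.
#' @param relax_quartile_min Lowest quality quartile admitted when relaxing.
#' @param relax_overlap_max_nt Largest tolerated pairwise overlap (nt) in the
#'   final relaxation stage; must be smaller than the guide length.
#' @param guide_length Spacer length in nucleotides.
#' @param flank5,flank3 Constant flanking sequences added around each spacer
#'   in the synthesis oligo (may be empty).
#' @param spacer_as Either `"target_site"` (store the protospacer, i.e. the
#'   targeted transcript window, the default) or `"reverse_complement"`
#'   (store the crRNA spacer itself) when emitting oligos.
#' @return A validated `cas13_design_config` list.
#' @export
#' @examples
#' design_config(flank5 = "AAAC", flank3 = "GTTT")
design_config <- function(target_per_transcript = 10L,
                          min_guides = 5L,
                          relax_quartile_min = 3L,
                          relax_overlap_max_nt = 10L,
                          guide_length = 23L,
                          flank5 = "",
                          flank3 = "",
                          spacer_as = c("target_site", "reverse_complement")) {
  assert_count(target_per_transcript, "target_per_transcript")
  assert_count(min_guides, "min_guides")
  assert_that(min_guides <= target_per_transcript,
              "`min_guides` must be <= `target_per_transcript`")
  assert_count(relax_quartile_min, "relax_quartile_min")
  assert_that(relax_quartile_min %in% 1:4, "`relax_quartile_min` must be in 1..4")
  assert_count(relax_overlap_max_nt, "relax_overlap_max_nt", min = 0L)
  assert_count(guide_length, "guide_length", min = 1L)
  assert_that(relax_overlap_max_nt < guide_length,
              "`relax_overlap_max_nt` must be smaller than `guide_length`")
  assert_that(is.character(flank5) && length(flank5) == 1L && !is.na(flank5) &&
                grepl("^[ACGT]*$", flank5), "`flank5` must be an ACGT string (possibly empty)")
  assert_that(is.character(flank3) && length(flank3) == 1L && !is.na(flank3) &&
                grepl("^[ACGT]*$", flank3), "`flank3` must be an ACGT string (possibly empty)")
  spacer_as <- match.arg(spacer_as)
  structure(
    list(target_per_transcript = as.integer(target_per_transcript),
         min_guides = as.integer(min_guides),
         relax_quartile_min = as.integer(relax_quartile_min),
         relax_overlap_max_nt = as.integer(relax_overlap_max_nt),
         guide_length = as.integer(guide_length),
         flank5 = flank5, flank3 = flank3, spacer_as = spacer_as),
    class = "cas13_design_config"
  )
}

#' Configuration for off-target scanning
#'
#' A guide has an off-target hit when a contiguous substring covering at
#' least `min_coverage` of its length matches a reference window outside its
#' own gene with at most `max_mismatches` mismatches (ungapped Hamming
#' matching; ambiguity codes in the reference count as mismatches).
#'
#' @param max_mismatches Maximum tolerated mismatches per placement.
#' @param min_coverage Minimum fraction of the guide that must align
#'   (aligned length >= ceiling(min_coverage * guide length)).
#' @param scan_both_strands Scan the reverse complement of each reference as
#'   well; use `TRUE` for genomic references, `FALSE` for a transcriptome
#'   (Cas13 targets the sense transcript).
#' @param seed_kmer_length Exact-match seed length for the production
#'   scanner. `NULL` (default) picks the pigeonhole bound
#'   `floor(min_aligned_length / (max_mismatches + 1))`; any explicit value
#'   must not exceed that bound or hits could be missed.
#' @return A validated `cas13_scan_config` list.
#' @export
#' @examples
#' scan_config(scan_both_strands = TRUE)
scan_config <- function(max_mismatches = 2L,
                        min_coverage = 0.90,
                        scan_both_strands = FALSE,
                        seed_kmer_length = NULL) {
  assert_count(max_mismatches, "max_mismatches", min = 0L)
  assert_number(min_coverage, "min_coverage", min = 0, max = 1, strict_min = TRUE)
  assert_that(is.logical(scan_both_strands) && length(scan_both_strands) == 1L &&
                !is.na(scan_both_strands), "`scan_both_strands` must be TRUE or FALSE")
  if (!is.null(seed_kmer_length)) assert_count(seed_kmer_length, "seed_kmer_length")
  structure(
    list(max_mismatches = as.integer(max_mismatches),
         min_coverage = min_coverage,
         scan_both_strands = scan_both_strands,
         seed_kmer_length = if (is.null(seed_kmer_length)) NULL else as.integer(seed_kmer_length)),
    class = "cas13_scan_config"
  )
}

min_aligned_length <- function(guide_length, min_coverage) {
  as.integer(ceiling(min_coverage * guide_length - 1e-9))
}
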