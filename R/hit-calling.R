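# gene-level hit calling: mean-variance modelling, negative-binomial guide
# tails, alpha-robust-rank-aggregation, permutation p-values, BH FDR

#' Fit a mean-variance model on baseline replicates
#'
#' Models overdispersion as `sigma^2(mu) = mu + exp(a) * mu^b`, fitted by
#' least squares of `log(max(s2 - mu, 0.01))` on `log(mu)` over guides with
#' positive mean, where `mu` and `s2` are the per-guide mean and sample
#' variance across baseline replicates of normalized counts.
#'
#' @param baseline Numeric matrix or data frame of normalized baseline
#'   counts, guides in rows, >= 2 replicate columns; >= 50 guides with
#'   positive mean are required.
#' @return A `cas13_meanvar` object with coefficients `a`, `b`.
#' @export
fit_mean_variance <- function(baseline) {
  m <- as.matrix(baseline)
  storage.mode(m) <- "double"
  assert_that(ncol(m) >= 2, "at least two baseline replicates are required")
  mu <- rowMeans(m)
  s2 <- apply(m, 1, var)
  use <- mu > 0
  assert_that(sum(use) >= 50,
              "at least 50 guides with positive baseline mean are required")
  fit <- lm(log(pmax(s2[use] - mu[use], 0.01)) ~ log(mu[use]))
  structure(
    list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         n_guides = sum(use), mu_range = range(mu[use])),
    class = "cas13_meanvar"
  )
}

#' Modeled count variance at a given mean
#'
#' @param model A [fit_mean_variance()] object.
#' @param mu Mean normalized count(s).
#' @return `mu + exp(a) * mu^b`, elementwise.
#' @export
predict_variance <- function(model, mu) {
  assert_that(inherits(model, "cas13_meanvar"), "`model` must come from fit_mean_variance()")
  mu + exp(model$a) * mu^model$b
}

#' Negative-binomial tail test for one guide
#'
#' The treatment replicate sum `x` is compared with a negative-binomial null
#' with mean `n_treat * mu` and variance `n_treat * sigma^2(mu)` from the
#' mean-variance model (collapsing to Poisson when the modeled variance does
#' not exceed the mean). Both tails include the observation: `p_high =
#' P(X >= x)` (enrichment) and `p_low = P(X <= x)` (depletion).
#'
#' @param mu Baseline mean normalized count per guide (> 0); vectorized.
#' @param x Observed treatment count sum per guide (rounded to integers).
#' @param n_treat Number of treatment replicates summed into `x`.
#' @param model A [fit_mean_variance()] object.
#' @return Tibble: p_low, p_high — both in (0, 1].
#' @export
#' @examples
#' mv <- structure(list(a = -Inf, b = 0), class = "cas13_meanvar")  # Poisson
#' nb_guide_test(1, 0, 1, mv)  # p_low = exp(-1)
nb_guide_test <- function(mu, x, n_treat, model) {
  assert_that(all(mu > 0), "guides with zero baseline mean must be excluded upstream")
  assert_that(length(x) == length(mu), "`mu` and `x` must have equal length")
  x <- round(x)
  m <- n_treat * mu
  v <- n_treat * predict_variance(model, mu)
  pois <- v <= m
  p_low <- numeric(length(mu))
  p_high <- numeric(length(mu))
  if (any(pois)) {
    p_low[pois] <- ppois(x[pois], m[pois])
    p_high[pois] <- ppois(x[pois] - 1, m[pois], lower.tail = FALSE)
  }
  if (any(!pois)) {
    size <- m[!pois]^2 / (v[!pois] - m[!pois])
    p_low[!pois] <- pnbinom(x[!pois], size = size, mu = m[!pois])
    p_high[!pois] <- pnbinom(x[!pois] - 1, size = size, mu = m[!pois],
                             lower.tail = FALSE)
  }
  # extreme tails can underflow; keep p-values strictly positive
  tibble(p_low = pmax(p_low, .Machine$double.xmin),
         p_high = pmax(p_high, .Machine$double.xmin))
}

#' Alpha-RRA gene score from normalized guide ranks
#'
#' Only guides ranked in the top `alpha` fraction contribute. With the gene's
#' normalized ranks sorted ascending and truncated at `alpha`, the score is
#' the minimum over j of `pbeta(rho_j, j, n_g - j + 1)` — the probability
#' that the j-th of `n_g` uniform order statistics falls at or below
#' `rho_j`. Genes with no guide inside `alpha` score 1.
#'
#' @param rho Normalized ranks in (0, 1] of one gene's guides (rank / total
#'   guides, ranks from a stable sort by (p, crRNA_id)).
#' @param alpha Rank-fraction cutoff.
#' @return Score in (0, 1]; smaller means stronger, more consistent guide
#'   support.
#' @export
#' @examples
#' alpha_rra_score(c(0.01, 0.02))  # min(1 - 0.99^2, 0.02^2)
alpha_rra_score <- function(rho, alpha = 0.25) {
  assert_that(length(rho) >= 1, "gene must have at least one guide")
  assert_that(all(rho > 0 & rho <= 1), "normalized ranks must lie in (0, 1]")
  assert_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  n_g <- length(rho)
  keep <- sort(rho[rho <= alpha])
  if (length(keep) == 0) return(1)
  j <- seq_along(keep)
  min(pbeta(keep, j, n_g - j + 1))
}

# vectorized alpha-RRA over the rows of a (permutations x n_g) rank matrix
rra_score_rows <- function(R, alpha) {
  n_g <- ncol(R)
  if (n_g > 1) R <- t(apply(R, 1, sort))
  B <- matrix(1, nrow(R), n_g)
  for (j in seq_len(n_g)) {
    inside <- R[, j] <= alpha
    B[inside, j] <- pbeta(R[inside, j], j, n_g - j + 1)
  }
  scores <- do.call(pmin, as.data.frame(B))
  # rows where no rank fell inside alpha keep score 1
  none <- rowSums(R <= alpha) == 0
  scores[none] <- 1
  scores
}

#' Permutation p-values for alpha-RRA gene scores
#'
#' For each distinct guide count `n_g`, draws `n_perm` sets of `n_g`
#' normalized ranks without replacement from the observed rank pool,
#' recomputes the score, and reports the add-one permutation p-value
#' `(1 + #[perm <= observed]) / (n_perm + 1)` per gene. The smallest
#' attainable p is therefore `1 / (n_perm + 1)`.
#'
#' @param scores Observed gene scores.
#' @param n_guides Guide count per gene (same length as `scores`).
#' @param pool Observed normalized rank pool (all tested guides).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Rank-fraction cutoff used for the scores.
#' @param seed Integer seed.
#' @return Numeric p-values in (0, 1].
#' @export
permutation_pvalues <- function(scores, n_guides, pool, n_perm = 10000L,
                                alpha = 0.25, seed = 1L) {
  assert_that(length(scores) == length(n_guides),
              "`scores` and `n_guides` must have equal length")
  assert_count(n_perm, "n_perm", min = 100L)
  assert_seed(seed)
  withr::with_seed(seed, {
    p <- numeric(length(scores))
    for (n_g in sort(unique(n_guides))) {
      R <- matrix(0, n_perm, n_g)
      for (i in seq_len(n_perm)) R[i, ] <- sample(pool, n_g)
      perm_sorted <- sort(rra_score_rows(R, alpha))
      idx <- which(n_guides == n_g)
      p[idx] <- (1 + findInterval(scores[idx], perm_sorted)) / (n_perm + 1)
    }
    p
  })
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity via [stats::p.adjust()];
#' output lies in `[p, 1]`.
#'
#' @param p P-values in (0, 1].
#' @return Adjusted FDR values.
#' @export
#' @examples
#' bh_adjust(c(0.002, 0.01, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  assert_that(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes as positive / negative hits
#'
#' A gene is a positive hit when `fdr_pos <= fdr_threshold` (guide
#' enrichment: knockdown increased proliferation) and a negative hit when
#' `fdr_neg <= fdr_threshold`. If both directions pass, the direction with
#' the smaller permutation p wins and the gene is flagged ambiguous.
#'
#' @param gene_results Tibble with p_pos, p_neg, fdr_pos, fdr_neg.
#' @param fdr_threshold High-confidence FDR cutoff (default 0.3).
#' @return The input with `hit_class` (positive / negative / none) and
#'   `ambiguous` columns.
#' @export
call_hits <- function(gene_results, fdr_threshold = 0.3) {
  assert_columns(gene_results, c("p_pos", "p_neg", "fdr_pos", "fdr_neg"), "gene_results")
  assert_number(fdr_threshold, "fdr_threshold", min = 0, max = 1)
  gene_results %>%
    dplyr::mutate(
      pos_pass = .data$fdr_pos <= fdr_threshold,
      neg_pass = .data$fdr_neg <= fdr_threshold,
      ambiguous = .data$pos_pass & .data$neg_pass,
      hit_class = dplyr::case_when(
        pos_pass & neg_pass & p_pos <= p_neg ~ "positive",
        pos_pass & neg_pass ~ "negative",
        pos_pass ~ "positive",
        neg_pass ~ "negative",
        TRUE ~ "none"
      )
    ) %>%
    dplyr::select(-"pos_pass", -"neg_pass")
}

#' Flag differentially represented guides
#'
#' Marks a guide enriched when `lfc > lfc_min` and `p_high < p_max`, and
#' depleted when `lfc < -lfc_min` and `p_low < p_max` (the red/blue dots of a
#' screen scatterplot).
#'
#' @param guide_stats Tibble with lfc, p_low, p_high.
#' @param lfc_min Absolute log2 fold-change threshold (default 0.1).
#' @param p_max Tail p-value threshold (default 0.05).
#' @return The input with a `flag` column (enriched / depleted / none).
#' @export
flag_guides <- function(guide_stats, lfc_min = 0.1, p_max = 0.05) {
  assert_columns(guide_stats, c("lfc", "p_low", "p_high"), "guide_stats")
  guide_stats %>%
    dplyr::mutate(flag = dplyr::case_when(
      .data$lfc > lfc_min & .data$p_high < p_max ~ "enriched",
      .data$lfc < -lfc_min & .data$p_low < p_max ~ "depleted",
      TRUE ~ "none"
    ))
}

#' Guide- and gene-level screen test
#'
#' The full differential-abundance analysis: median-ratio normalization,
#' baseline mean-variance fitting, per-guide negative-binomial tail tests of
#' the summed treatment counts against the baseline mean, guide log2
#' fold-changes, alpha-RRA gene scores in both directions with permutation
#' p-values, BH FDR, and hit classification at `fdr_threshold`.
#'
#' Guides with zero baseline mean are excluded (reported in
#' `excluded_guides`); normalized guide ranks use a stable sort by
#' (p, crRNA_id) so results are fully deterministic given `seed`.
#'
#' @param counts Wide count tibble (crRNA_id, gene_id, sample columns).
#' @param baseline,treatment Sample column names of the two timepoints.
#' @param alpha Alpha-RRA rank-fraction cutoff.
#' @param n_perm Permutations for gene p-values.
#' @param fdr_threshold Hit-calling FDR cutoff.
#' @param seed Integer seed for the permutations.
#' @return A `cas13_screen_test` object: `guide_stats` (crRNA_id, gene_id,
#'   base_mean, treat_mean, lfc, p_low, p_high, rho_pos, rho_neg, flag),
#'   `gene_results` (gene_id, n_guides, gene_lfc, score/p/fdr per direction,
#'   hit_class), `excluded_guides`, `size_factors`, `meanvar`, and the call
#'   parameters.
#' @export
screen_test <- function(counts, baseline, treatment, alpha = 0.25,
                        n_perm = 10000L, fdr_threshold = 0.3, seed = 1L) {
  assert_columns(counts, c("crRNA_id", "gene_id"), "counts")
  assert_columns(counts, c(baseline, treatment), "counts")
  assert_that(length(baseline) >= 2, "at least two baseline replicates are required")
  assert_that(length(treatment) >= 1, "at least one treatment sample is required")
  assert_seed(seed)

  norm <- median_ratio_normalize(counts, c(baseline, treatment))
  nm <- count_matrix(norm$normalized, c(baseline, treatment))
  base_m <- nm[, baseline, drop = FALSE]
  treat_m <- nm[, treatment, drop = FALSE]
  meanvar <- fit_mean_variance(base_m)

  base_mean <- rowMeans(base_m)
  treat_mean <- rowMeans(treat_m)
  excluded <- counts$crRNA_id[base_mean == 0]
  keep <- base_mean > 0

  gs <- tibble(
    crRNA_id = counts$crRNA_id[keep],
    gene_id = counts$gene_id[keep],
    base_mean = base_mean[keep],
    treat_mean = treat_mean[keep]
  )
  tails <- nb_guide_test(gs$base_mean, rowSums(treat_m)[keep],
                         length(treatment), meanvar)
  gs$p_low <- tails$p_low
  gs$p_high <- tails$p_high
  gs$lfc <- log2((gs$treat_mean + 1) / (gs$base_mean + 1))

  m <- nrow(gs)
  rank_of <- function(p) {
    ord <- order(p, gs$crRNA_id)
    r <- integer(m)
    r[ord] <- seq_len(m)
    r / m
  }
  gs$rho_pos <- rank_of(gs$p_high)
  gs$rho_neg <- rank_of(gs$p_low)
  gs <- flag_guides(gs)

  genes <- gs %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_guides = dplyr::n(),
      gene_lfc = median(.data$lfc),
      score_pos = alpha_rra_score(.data$rho_pos, alpha),
      score_neg = alpha_rra_score(.data$rho_neg, alpha),
      .groups = "drop"
    )
  pool <- seq_len(m) / m
  genes$p_pos <- permutation_pvalues(genes$score_pos, genes$n_guides, pool,
                                     n_perm = n_perm, alpha = alpha, seed = seed)
  genes$p_neg <- permutation_pvalues(genes$score_neg, genes$n_guides, pool,
                                     n_perm = n_perm, alpha = alpha, seed = seed + 1L)
  genes$fdr_pos <- bh_adjust(genes$p_pos)
  genes$fdr_neg <- bh_adjust(genes$p_neg)
  genes <- call_hits(genes, fdr_threshold)

  structure(
    list(
      guide_stats = gs,
      gene_results = genes,
      excluded_guides = excluded,
      size_factors = norm$size_factors,
      meanvar = meanvar,
      params = list(baseline = baseline, treatment = treatment, alpha = alpha,
                    n_perm = as.integer(n_perm), fdr_threshold = fdr_threshold,
                    seed = as.integer(seed))
    ),
    class = "cas13_screen_test"
  )
}

#' @export
print.cas13_screen_test <- function(x, ...) {
  tab <- table(x$gene_results$hit_class)
  cat("Pooled screen test\n")
  cat(sprintf("  %d guides (%d excluded), %d genes\n",
              nrow(x$guide_stats), length(x$excluded_guides),
              nrow(x$gene_results)))
  cat(sprintf("  hits at FDR <= %.2f: %d positive, %d negative\n",
              x$params$fdr_threshold,
              if ("positive" %in% names(tab)) tab[["positive"]] else 0L,
              if ("negative" %in% names(tab)) tab[["negative"]] else 0L))
  invisible(x)
}

#' Re-run hit calling after off-target filtering
#'
#' Runs the full screen test twice — on all guides, and on the library minus
#' the removed guides — and reports both result sets, genes whose hit class
#' changed, and genes dropped because every guide was removed.
#'
#' @param counts Wide count tibble.
#' @param removals Character vector of removed crRNA ids (e.g. from
#'   [filter_library()]'s report).
#' @param ... Passed to [screen_test()] (baseline, treatment, alpha, n_perm,
#'   fdr_threshold, seed).
#' @return A list: `initial`, `filtered` (both `cas13_screen_test`),
#'   `changed` (tibble gene_id, hit_class_initial, hit_class_filtered), and
#'   `dropped_genes`.
#' @export
rerun_after_filter <- function(counts, removals, ...) {
  assert_that(is.character(removals), "`removals` must be a character vector of crRNA ids")
  unknown <- setdiff(removals, counts$crRNA_id)
  assert_that(length(unknown) == 0,
              sprintf("removals not present in counts: %s",
                      paste(head(unknown, 5), collapse = ", ")))
  initial <- screen_test(counts, ...)
  kept <- counts[!counts$crRNA_id %in% removals, , drop = FALSE]
  dropped_genes <- setdiff(counts$gene_id, kept$gene_id)
  if (length(dropped_genes) > 0) {
    warn(sprintf("%d gene(s) lost all guides and were dropped from the filtered run",
                 length(dropped_genes)))
  }
  filtered <- screen_test(kept, ...)
  changed <- dplyr::inner_join(
    initial$gene_results %>% dplyr::select("gene_id", hit_class_initial = "hit_class"),
    filtered$gene_results %>% dplyr::select("gene_id", hit_class_filtered = "hit_class"),
    by = "gene_id"
  ) %>%
    dplyr::filter(.data$hit_class_initial != .data$hit_class_filtered)
  list(initial = initial, filtered = filtered, changed = changed,
       dropped_genes = dropped_genes)
}
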