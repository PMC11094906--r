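# downstream statistics: RNA half-life from transcription-shutoff time
# courses, and RNA pull-down enrichment filtering/ranking

#' Fit first-order RNA decay
#'
#' Ordinary least squares of `ln(abundance)` on time (free intercept); the
#' decay constant is minus the slope and the half-life is `ln(2) / k`. A
#' non-decaying series (slope >= 0) is flagged and reported with infinite
#' half-life.
#'
#' @param series Data frame with columns `t_hours` and `rel_abundance`
#'   (> 0); at least three timepoints.
#' @param allele Optional label carried into the fit.
#' @return A `cas13_decay_fit` object: allele, k_decay (per hour), t_half
#'   (hours), r_squared, n_points, decaying flag.
#' @export
#' @examples
#' s <- simulate_decay(decay_sim_params(noise_sd = 0))
#' fit_decay(s[s$allele == "protective", ], allele = "protective")
fit_decay <- function(series, allele = NA_character_) {
  assert_columns(series, c("t_hours", "rel_abundance"), "series")
  assert_that(nrow(series) >= 3, "at least three timepoints are required")
  assert_that(all(is.finite(series$t_hours)), "timepoints must be finite")
  assert_that(all(is.finite(series$rel_abundance)) && all(series$rel_abundance > 0),
              "abundances must be positive (log of zero is undefined)")
  fit <- lm(log(rel_abundance) ~ t_hours, data = series)
  k <- -unname(coef(fit)[2])
  decaying <- k > 0
  structure(
    list(
      allele = allele,
      k_decay = k,
      t_half = if (decaying) log(2) / k else Inf,
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = nrow(series),
      decaying = decaying
    ),
    class = "cas13_decay_fit"
  )
}

#' @export
print.cas13_decay_fit <- function(x, ...) {
  cat(sprintf("RNA decay fit%s: k = %.4f /h, t1/2 = %.3f h (R^2 = %.3f, n = %d)%s\n",
              if (is.na(x$allele)) "" else paste0(" [", x$allele, "]"),
              x$k_decay, x$t_half, x$r_squared, x$n_points,
              if (x$decaying) "" else "  [non-decaying]"))
  invisible(x)
}

#' Compare allele-specific half-lives
#'
#' @param fit_risk,fit_protective Valid (decaying) [fit_decay()] objects for
#'   the two alleles.
#' @return Tibble: t_half_risk, t_half_protective, ratio
#'   (`t_half_risk / t_half_protective`), log2_ratio.
#' @export
compare_alleles <- function(fit_risk, fit_protective) {
  assert_that(inherits(fit_risk, "cas13_decay_fit") &&
                inherits(fit_protective, "cas13_decay_fit"),
              "both arguments must come from fit_decay()")
  assert_that(fit_risk$decaying && fit_protective$decaying,
              "both series must be decaying to compare half-lives")
  ratio <- fit_risk$t_half / fit_protective$t_half
  tibble(
    t_half_risk = fit_risk$t_half,
    t_half_protective = fit_protective$t_half,
    ratio = ratio,
    log2_ratio = log2(ratio)
  )
}

#' Filter and rank pull-down enrichment
#'
#' Per protein, a two-sided one-sample t-test of the replicate log2 ratios
#' over the control capture against 0; a protein passes when it has at least
#' `peptide_min` identified peptides, mean log2 fold-change above `lfc_min`,
#' and p below `p_max`. Passers are ranked by mean fold-change, descending.
#' Zero-variance replicate sets with nonzero mean are reported at the machine
#' floor with a flag.
#'
#' @param table Wide tibble: `protein_id`, `n_peptides`, and replicate
#'   columns named `rep1`, `rep2`, ... (log2 ratios; >= 2 replicates).
#' @param peptide_min Minimum identified peptides (default 5).
#' @param lfc_min Mean log2 fold-change threshold (default 2).
#' @param p_max P-value threshold (default 0.05).
#' @return Tibble: protein_id, n_peptides, mean_log2fc, t_statistic, p_value,
#'   zero_variance, passes_filters, rank (NA for non-passers).
#' @export
#' @examples
#' pd <- simulate_pulldown(20, 3, seed = 1)
#' rank_pulldown(pd)
rank_pulldown <- function(table, peptide_min = 5L, lfc_min = 2, p_max = 0.05) {
  assert_columns(table, c("protein_id", "n_peptides"), "table")
  rep_cols <- grep("^rep[0-9]+$", names(table), value = TRUE)
  assert_that(length(rep_cols) >= 2, "at least two replicate columns (rep1, rep2, ...) are required")
  assert_that(all(table$n_peptides >= 0), "peptide counts must be non-negative")
  ratios <- as.matrix(table[, rep_cols])
  storage.mode(ratios) <- "double"

  res <- purrr::map_dfr(seq_len(nrow(ratios)), function(i) {
    x <- ratios[i, ]
    if (var(x) == 0) {
      tibble(
        mean_log2fc = mean(x),
        t_statistic = if (mean(x) == 0) 0 else sign(mean(x)) * Inf,
        p_value = if (mean(x) == 0) 1 else .Machine$double.xmin,
        zero_variance = TRUE
      )
    } else {
      tt <- t.test(x, mu = 0, alternative = "two.sided")
      tibble(
        mean_log2fc = mean(x),
        t_statistic = unname(tt$statistic),
        p_value = tt$p.value,
        zero_variance = FALSE
      )
    }
  })
  out <- dplyr::bind_cols(
    table[, c("protein_id", "n_peptides")],
    res
  ) %>%
    dplyr::mutate(
      passes_filters = .data$n_peptides >= peptide_min &
        .data$mean_log2fc > lfc_min &
        .data$p_value < p_max
    ) %>%
    dplyr::arrange(dplyr::desc(.data$passes_filters),
                   dplyr::desc(.data$mean_log2fc), .data$protein_id)
  out$rank <- NA_integer_
  out$rank[out$passes_filters] <- seq_len(sum(out$passes_filters))
  out
}
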