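# broom-style tidiers so results drop into tidyverse workflows

#' Tidy a decay fit
#'
#' @param x A [fit_decay()] object.
#' @param ... Unused.
#' @return One-row tibble: allele, k_decay, t_half, r_squared, n_points,
#'   decaying.
#' @method tidy cas13_decay_fit
#' @export
tidy.cas13_decay_fit <- function(x, ...) {
  tibble(allele = x$allele, k_decay = x$k_decay, t_half = x$t_half,
         r_squared = x$r_squared, n_points = x$n_points, decaying = x$decaying)
}

#' @rdname tidy.cas13_decay_fit
#' @method glance cas13_decay_fit
#' @export
glance.cas13_decay_fit <- function(x, ...) tidy.cas13_decay_fit(x)

#' Tidy a mean-variance model
#'
#' @param x A [fit_mean_variance()] object.
#' @param ... Unused.
#' @return One-row tibble with the coefficients of
#'   `sigma^2 = mu + exp(a) * mu^b`.
#' @method tidy cas13_meanvar
#' @export
tidy.cas13_meanvar <- function(x, ...) {
  tibble(a = x$a, b = x$b, n_guides = x$n_guides,
         mu_min = x$mu_range[1], mu_max = x$mu_range[2])
}

#' Gene-level results of a screen test
#'
#' @param x A [screen_test()] object.
#' @param ... Unused.
#' @return `tidy()`: the gene results tibble. `glance()`: one row with gene
#'   and guide totals and hit counts at the configured FDR.
#' @method tidy cas13_screen_test
#' @export
tidy.cas13_screen_test <- function(x, ...) x$gene_results

#' @rdname tidy.cas13_screen_test
#' @method glance cas13_screen_test
#' @export
glance.cas13_screen_test <- function(x, ...) {
  tibble(
    n_guides = nrow(x$guide_stats),
    n_excluded = length(x$excluded_guides),
    n_genes = nrow(x$gene_results),
    n_positive = sum(x$gene_results$hit_class == "positive"),
    n_negative = sum(x$gene_results$hit_class == "negative"),
    fdr_threshold = x$params$fdr_threshold
  )
}

#' Tidy screen QC
#'
#' @param x A [screen_qc()] object.
#' @param ... Unused.
#' @return `tidy()`: per-sample statistics joined with pairwise correlations.
#'   `glance()`: one row with the worst-case statistics against the usual
#'   screen quality bounds (Gini < 0.1, replicate r > 0.9).
#' @method tidy cas13_qc
#' @export
tidy.cas13_qc <- function(x, ...) x$sample_stats

#' @rdname tidy.cas13_qc
#' @method glance cas13_qc
#' @export
glance.cas13_qc <- function(x, ...) {
  tibble(
    n_samples = nrow(x$sample_stats),
    max_gini = max(x$sample_stats$gini),
    min_correlation = x$min_correlation,
    gini_pass = max(x$sample_stats$gini) < 0.1,
    correlation_pass = !is.na(x$min_correlation) && x$min_correlation > 0.9
  )
}
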