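# ggplot2 views of the pipeline's result objects

#' Guide scatterplot of a screen test
#'
#' Log2 fold-change against baseline abundance, coloured by the guide flag
#' (enriched / depleted / none).
#'
#' @param object A [screen_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cas13_screen_test
#' @export
autoplot.cas13_screen_test <- function(object, ...) {
  ggplot2::ggplot(object$guide_stats,
                  ggplot2::aes(x = log2(.data$base_mean + 1), y = .data$lfc,
                               colour = .data$flag)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(enriched = "#c0392b", depleted = "#2980b9", none = "grey70")
    ) +
    ggplot2::labs(x = "log2 baseline mean + 1", y = "guide log2 fold-change",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' QC overview plot
#'
#' Per-sample Gini indices with the 0.1 evenness bound, and pairwise
#' replicate correlations with the 0.9 bound.
#'
#' @param object A [screen_qc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cas13_qc
#' @export
autoplot.cas13_qc <- function(object, ...) {
  gini_df <- dplyr::mutate(object$sample_stats, metric = "Gini index",
                           value = .data$gini, label = .data$sample_id)
  cor_df <- dplyr::mutate(object$correlations, metric = "replicate r",
                          value = .data$r,
                          label = paste(.data$sample_a, .data$sample_b, sep = " / "))
  bounds <- tibble(metric = c("Gini index", "replicate r"), bound = c(0.1, 0.9))
  df <- dplyr::bind_rows(gini_df[, c("metric", "value", "label")],
                         cor_df[, c("metric", "value", "label")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(data = bounds, ggplot2::aes(yintercept = .data$bound),
                        linetype = "dashed", colour = "#c0392b") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Decay time-course plot
#'
#' Log-scale abundance with the fitted exponential.
#'
#' @param series Decay tibble (allele, t_hours, rel_abundance).
#' @param fits Optional named list of [fit_decay()] objects keyed by allele.
#' @return A ggplot.
#' @export
plot_decay <- function(series, fits = NULL) {
  assert_columns(series, c("allele", "t_hours", "rel_abundance"), "series")
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$t_hours, y = .data$rel_abundance,
                                    colour = .data$allele)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "hours after transcription block",
                  y = "relative abundance", colour = "allele") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    tmax <- max(series$t_hours)
    lines <- purrr::imap_dfr(fits, function(f, allele) {
      t <- seq(0, tmax, length.out = 50)
      tibble(allele = allele, t_hours = t, rel_abundance = exp(-f$k_decay * t))
    })
    p <- p + ggplot2::geom_line(data = lines, linetype = "dashed")
  }
  p
}

#' Pull-down enrichment plot
#'
#' Mean log2 fold-change against -log10 p, with the filter box.
#'
#' @param results A [rank_pulldown()] table.
#' @param lfc_min,p_max The thresholds to draw.
#' @return A ggplot.
#' @export
plot_pulldown <- function(results, lfc_min = 2, p_max = 0.05) {
  assert_columns(results, c("mean_log2fc", "p_value", "passes_filters"), "results")
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$mean_log2fc, y = -log10(.data$p_value),
                               colour = .data$passes_filters)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = lfc_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    ggplot2::labs(x = "mean log2 fold-change over control", y = "-log10 p",
                  colour = "passes filters") +
    ggplot2::theme_minimal()
}
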