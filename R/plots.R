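# ggplot2 helpers mirroring the analysis' standard displays.

#' Scatter plot of methylation change versus expression (or accessibility)
#' change
#'
#' @param object A `methylens_cor` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methylens_cor <- function(object, ...) {
  dat <- object$data
  ycol <- if ("log2fc" %in% names(dat)) "log2fc" else "peak_log2fc"
  ggplot2::ggplot(dat, ggplot2::aes(.data$avg_diff_methyl, .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "red") +
    ggplot2::labs(
      x = "Average diff. methyl (fiber - epi)",
      y = "log2 fold change (fiber / epi)",
      subtitle = sprintf("Pearson r = %.2f, p = %.2g, n = %d",
                         object$r, object$p_value, object$n)
    ) +
    ggplot2::theme_classic()
}

#' Stacked-bar view of a 2-way association table
#'
#' @param object A `methylens_assoc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methylens_assoc <- function(object, ...) {
  dat <- tidy(object)
  nm <- names(dat)
  ggplot2::ggplot(dat, ggplot2::aes(.data[[nm[1]]], .data$n,
                                    fill = .data[[nm[2]]])) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%d%%", round(100 * x))) +
    ggplot2::labs(y = "Proportion of genes/sites",
                  subtitle = if (is.na(object$statistic)) NULL else
                    sprintf("Chi-square = %.3g, p = %.2g",
                            object$statistic, object$p_value)) +
    ggplot2::theme_classic()
}

#' Observed-versus-random DMR category distribution
#'
#' Bar chart of per-category percentage-point differences between the
#' observed DMR distribution and the random-placement expectation.
#'
#' @param object A `methylens_null` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.methylens_null <- function(object, ...) {
  ggplot2::ggplot(object$comparison,
                  ggplot2::aes(.data$category, .data$pct_difference)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Observed - expected (% of DMRs)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bubble plot of motif enrichment results
#'
#' Enrichment strength (-log10 adjusted p) against the number of target
#' genes, coloured by the TF gene's expression class and sized by its total
#' FPKM, mirroring the standard display for expression-filtered motif
#' enrichment.
#'
#' @param results Annotated enrichment tibble from
#'   [annotate_tf_expression()].
#' @return A ggplot.
#' @export
plot_motif_enrichment <- function(results) {
  dat <- filter(results, !is.na(.data$adjusted_p))
  ggplot2::ggplot(dat, ggplot2::aes(-log10(.data$adjusted_p),
                                    .data$n_target_genes)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = .data$tf_deg_class,
      size = .data$tf_total_fpkm
    ), alpha = 0.7) +
    ggplot2::labs(x = "-log10 adjusted p", y = "Target genes with a site",
                  colour = "TF gene class", size = "TF total FPKM") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
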