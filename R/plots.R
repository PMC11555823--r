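#' @importFrom ggplot2 ggplot aes geom_point geom_boxplot geom_hline
#'   geom_tile facet_grid labs scale_fill_gradient2 theme_minimal autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a DE result
#'
#' @param de A `de_result` tibble.
#' @param alpha Adjusted-p significance threshold to highlight.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  d <- de |>
    filter(!is.na(.data$p_value)) |>
    mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
  ggplot(d, aes(.data$log2fc, -log10(.data$p_value),
                colour = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = "log2 fold-change", y = "-log10 p",
         title = attr(de, "contrast"), colour = sprintf("padj < %s", alpha)) +
    theme_minimal()
}

#' @method autoplot rescue_report
#' @export
autoplot.rescue_report <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(.data$arm, .data$treatment_log_ratio)) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_boxplot(outlier.size = 0.4) +
    facet_grid(. ~ direction,
               labeller = ggplot2::labeller(
                 direction = c(up = "up at baseline",
                               down = "down at baseline"))) +
    labs(x = NULL, y = "log2 (treated / affected control) pooled CPM") +
    theme_minimal()
}

#' @method autoplot signature_heatmap
#' @export
autoplot.signature_heatmap <- function(object, ...) {
  z <- object$z[object$row_order, object$col_order, drop = FALSE]
  d <- as_tibble(as.table(z), .name_repair = "minimal")
  names(d) <- c("gene", "sample", "z")
  d$gene <- factor(d$gene, levels = rownames(z))
  d$sample <- factor(d$sample, levels = colnames(z))
  ggplot(d, aes(.data$sample, .data$gene, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @method autoplot pc_shift
#' @export
autoplot.pc_shift <- function(object, ...) {
  s <- object$samples
  ggplot(s, aes(.data$cell_line, .data$delta,
                colour = .data$treatment, shape = .data$genotype)) +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_point() +
    labs(x = "cell line",
         y = sprintf("delta PC%d vs matched untreated", object$component)) +
    theme_minimal()
}

#' @method autoplot overlap_result
#' @export
autoplot.overlap_result <- function(object, ...) {
  d <- tidy(object) |> filter(.data$shared)
  ggplot(d, aes(.data$log2fc_a, .data$log2fc_b,
                colour = .data$concordance)) +
    geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    geom_point(alpha = 0.7) +
    labs(x = "log2 FC (this study)", y = "log2 FC (companion)",
         subtitle = sprintf("r = %.2f, p = %.2g; overlap p = %.2g",
                            object$pearson_r, object$pearson_p,
                            object$fisher_p)) +
    theme_minimal()
}
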