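#' Bar plot of DMR counts by context and direction
#'
#' @param dmrs A DMR tibble.
#' @return A ggplot object.
#' @export
plot_dmr_counts <- function(dmrs) {
  counts <- summarize_dmrs(dmrs)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$context, y = .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(hyper = "#1b9e77", hypo = "#7570b3")) +
    ggplot2::labs(x = "context", y = "DMRs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of methylation vs expression changes
#'
#' Mirrors the usual methylome-transcriptome integration display: expression
#' log2 fold change on x, methylation log2 fold change on y, coloured by the
#' sign regime of the product.
#'
#' @param pairs Pairs tibble from [associate_dmr_genes()].
#' @return A ggplot object.
#' @export
plot_meth_expr <- function(pairs) {
  dat <- pairs %>%
    mutate(set = dplyr::case_when(
      .data$meth_log2fc * .data$expr_log2fc > 0 ~ "positive",
      .data$meth_log2fc * .data$expr_log2fc < 0 ~ "negative",
      TRUE ~ "excluded"
    ))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expr_log2fc,
                                    y = .data$meth_log2fc,
                                    colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#b2182b",
                                            excluded = "grey50")) +
    ggplot2::labs(x = "expression log2 fold change",
                  y = "methylation log2 fold change", colour = NULL) +
    ggplot2::theme_minimal()
}
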