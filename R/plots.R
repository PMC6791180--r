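#' Plot sample PCA coordinates
#'
#' @param object A `sample_pca` from [sample_pca()].
#' @param colour_by Optional tibble (`sample_id` plus one grouping column,
#'   e.g. `caste` or `colony`) used to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sample_pca
#' @export
autoplot.sample_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  p <- if (!is.null(colour_by)) {
    grp <- setdiff(names(colour_by), "sample_id")[1]
    df <- left_join(df, colour_by, by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = .data[[grp]]))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot weighted methylation by genomic feature class
#'
#' Caste means with 95% confidence intervals across colonies, per feature
#' class, in the style of a feature-level methylation summary panel.
#'
#' @param summary Output of [feature_summary()].
#' @return A ggplot.
#' @export
plot_feature_methylation <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$feature_type, .data$W,
                               colour = .data$caste)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "feature", y = "weighted methylation level") +
    ggplot2::theme_minimal()
}

#' Caste-versus-caste scatter of gene weighted methylation
#'
#' Each point is a gene; the mean weighted methylation across colonies for
#' reproductive workers is plotted against sterile workers, with
#' differentially methylated genes highlighted.
#'
#' @param caste_w Gene-level output of [caste_methylation()].
#' @param dm_gene_ids Character vector of DM gene ids to highlight.
#' @return A ggplot.
#' @export
plot_caste_scatter <- function(caste_w, dm_gene_ids = character()) {
  wide <- caste_w |>
    select("gene_id", "caste", "W") |>
    tidyr::pivot_wider(names_from = "caste", values_from = "W") |>
    mutate(dm = .data$gene_id %in% dm_gene_ids)
  ggplot2::ggplot(wide, ggplot2::aes(.data$sterile, .data$reproductive,
                                     colour = .data$dm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 name = "differentially\nmethylated") +
    ggplot2::labs(x = "sterile W", y = "reproductive W") +
    ggplot2::theme_minimal()
}

#' Expression distribution across methylation bins
#'
#' @param data Tibble with `bin` and `expr` (log-scale expression), as passed
#'   to [expression_by_meth_bin()].
#' @return A ggplot.
#' @export
plot_meth_bins <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$bin, .data$expr)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
    ggplot2::labs(x = "methylation bin", y = "log expression") +
    ggplot2::theme_minimal()
}
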