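#' Plot torus clusters in a dihedral plane
#'
#' Scatter of suites in two of the seven backbone dihedrals, coloured by
#' cluster (outliers in grey). The alpha-beta plane usually separates
#' clusters best for the C3'-C3' pucker pair.
#'
#' @param suites Suite tibble with dihedral columns and a `cluster` column.
#' @param x,y Dihedral names (see [suite_dihedral_names()]).
#' @return A ggplot object.
#' @export
plot_torus_clusters <- function(suites, x = "alpha", y = "beta") {
  stopifnot(x %in% names(suites), y %in% names(suites))
  df <- suites
  df$cluster_f <- factor(ifelse(df$cluster == 0, "outlier", df$cluster))
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]], colour = .data$cluster_f)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 360, 90)) +
    ggplot2::scale_y_continuous(limits = c(0, 360), breaks = seq(0, 360, 90)) +
    ggplot2::labs(colour = "cluster", x = paste(x, "(deg)"), y = paste(y, "(deg)")) +
    ggplot2::theme_minimal()
}

#' Plot cluster summaries of a fitted classifier
#'
#' Mean pseudo-bond lengths of every trained cluster, sized by cluster
#' membership and faceted by pucker pair; a quick view of how the low-detail
#' cluster centres are laid out.
#'
#' @param object A `rnaprecis_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rnaprecis_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$d2, .data$d3, size = .data$n,
                                   label = .data$conformers)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_text(size = 3, vjust = -1) +
    ggplot2::facet_wrap(~pucker_pair) +
    ggplot2::labs(x = "mean d2 (A)", y = "mean d3 (A)", size = "members") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation summary
#'
#' Stacked per-pucker-pair bars of the three evaluation categories
#' (prediction match / prediction mismatch / pucker mismatch).
#'
#' @param evaluation Result of [precis_evaluate()].
#' @return A ggplot object.
#' @export
plot_evaluation <- function(evaluation) {
  df <- evaluation$records
  df <- df[!is.na(df$category), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$pucker_pair, fill = .data$category)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      prediction_match = "#3b6fb6", prediction_mismatch = "#c23b3b",
      pucker_mismatch = "#e08b2d"
    )) +
    ggplot2::labs(x = "pucker pair", y = "suites", fill = NULL) +
    ggplot2::theme_minimal()
}
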