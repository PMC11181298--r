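# ggplot2 displays for the main result types.

#' Bar plot of aggregated variance-partition percentages
#'
#' @param object A [variance_partition()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot variance_partition
#' @export
autoplot.variance_partition <- function(object, ...) {
  agg <- object$aggregated
  ggplot2::ggplot(agg, ggplot2::aes(
    x = stats::reorder(.data$factor, -.data$percent), y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of variance (top PCs)",
                  title = sprintf("Variance partition (%s ANOVA, K = %d)",
                                  object$mode, object$pca$K)) +
    ggplot2::theme_minimal()
}

#' MDS scatter of samples
#'
#' @param object A [classical_mds()] result.
#' @param cohort Optional cohort tibble; when given, points are colored by
#'   `colour_by`.
#' @param colour_by Cohort column used for color (default `"region"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_mds
#' @export
autoplot.meth_mds <- function(object, cohort = NULL, colour_by = "region", ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(cohort)) {
    df <- dplyr::left_join(df, cohort, by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      .data$MDS1, .data$MDS2, colour = .data[[colour_by]]))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$MDS1, .data$MDS2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(title = "Classical MDS of methylation profiles") +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of association p values
#'
#' Observed versus expected -log10 p under the uniform null, annotated with
#' the genomic inflation factor.
#'
#' @param p Numeric vector of p values.
#' @return A ggplot.
#' @export
plot_qq <- function(p) {
  p <- sort(p[is.finite(p)])
  n <- length(p)
  lam <- genomic_lambda(p)$lambda
  df <- tibble::tibble(expected = -log10((seq_len(n) - 0.5) / n),
                       observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = sprintf("QQ plot (lambda = %.3f)", lam)) +
    ggplot2::theme_minimal()
}

#' Methylation-vs-expression scatter for DMR links
#'
#' @param object A link tibble from [link_dmrs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_links <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$meth_effect, .data$expr_logfc, colour = .data$promoter)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "DMR methylation effect (M-value, mood - control)",
                  y = "expression log2 fold change (mood - control)") +
    ggplot2::theme_minimal()
}
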