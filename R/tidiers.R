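# broom-style tidiers for the fitted result objects.

#' Tidy a variance-partition result
#'
#' One row per (PC, factor) with the ANOVA fraction and component variance.
#'
#' @param x A [variance_partition()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy variance_partition
#' @export
tidy.variance_partition <- function(x, ...) {
  tibble::as_tibble(x$per_pc)
}

#' One-row summary of a variance-partition result
#' @inheritParams tidy.variance_partition
#' @return A one-row tibble with one `percent_<factor>` column per factor,
#'   plus `k` and `mode`.
#' @method glance variance_partition
#' @export
glance.variance_partition <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregated, names_from = "factor",
                             values_from = "percent", names_prefix = "percent_")
  dplyr::bind_cols(wide, tibble::tibble(k = x$pca$K, mode = x$mode))
}

#' Tidy a PCA result
#' @param x A [pca_top()] result.
#' @param ... Unused.
#' @return A tibble: `pc`, `variance`, `proportion` (of total variance),
#'   `cumulative`.
#' @method tidy meth_pca
#' @export
tidy.meth_pca <- function(x, ...) {
  prop <- x$component_variances / x$total_variance
  tibble::tibble(pc = seq_len(x$K), variance = x$component_variances,
                 proportion = prop, cumulative = cumsum(prop))
}

#' One-row summary of a PCA result
#' @inheritParams tidy.meth_pca
#' @return A one-row tibble: `k`, `total_variance`, `prop_captured`.
#' @method glance meth_pca
#' @export
glance.meth_pca <- function(x, ...) {
  tibble::tibble(k = x$K, total_variance = x$total_variance,
                 prop_captured = sum(x$component_variances) / x$total_variance)
}

#' Tidy a link correlation
#' @param x A [correlate_links()] result.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `n`, `p.value`, `degenerate`.
#' @method tidy link_correlation
#' @export
tidy.link_correlation <- function(x, ...) {
  tibble::tibble(estimate = x$r, n = x$n, p.value = x$p,
                 degenerate = x$degenerate)
}
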