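# logCPM, expression filtering, the parallel differential-expression model,
# and DMR-to-expression linkage.

#' log counts per million
#'
#' `logCPM = log2((count + 0.5) / (library_size + 1) * 1e6)` with the library
#' size the per-sample column total.
#'
#' @param counts Gene x sample count matrix.
#' @return logCPM matrix of the same shape.
#' @export
log_cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort_dmrpipe(sprintf("sample(s) with zero library size: %s",
                          paste(colnames(counts)[libsize == 0], collapse = ", ")),
                  "dmrpipe_input_error")
  }
  out <- log2(sweep(counts + 0.5, 2, libsize + 1, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  out
}

#' Filter expressed genes
#'
#' A gene is retained iff its mean logCPM is at least `threshold` in the
#' control group AND in the mood-disorder group (inclusive `>=`).
#'
#' @param logcpm logCPM matrix (genes x samples).
#' @param cohort Cohort tibble.
#' @param threshold Mean logCPM threshold, default 1.
#' @return A tibble: `gene`, `mean_logcpm_control`, `mean_logcpm_mood`,
#'   `retained`.
#' @export
filter_expressed <- function(logcpm, cohort, threshold = 1) {
  cohort <- validate_cohort(cohort)
  logcpm <- align_to_cohort(logcpm, cohort, "logCPM matrix")
  mood <- cohort$mood_disorder
  if (!any(mood) || all(mood)) {
    abort_dmrpipe("both diagnostic groups must be non-empty", "dmrpipe_design_error")
  }
  mc <- rowMeans(logcpm[, !mood, drop = FALSE])
  mm <- rowMeans(logcpm[, mood, drop = FALSE])
  tibble::tibble(gene = rownames(logcpm),
                 mean_logcpm_control = unname(mc),
                 mean_logcpm_mood = unname(mm),
                 retained = unname(mc >= threshold & mm >= threshold))
}

#' Per-gene mixed model on logCPM
#'
#' The same donor random-intercept model as [fit_cpg_mixed()], applied to
#' logCPM rows; the mood-disorder coefficient is the log2 fold change.
#'
#' @param logcpm logCPM matrix (genes x samples).
#' @param cohort Cohort tibble.
#' @return A tibble: `gene`, `expr_logfc`, `se`, `t_stat`, `df`, `p`,
#'   `converged`.
#' @export
fit_gene_model <- function(logcpm, cohort) {
  stats <- fit_cpg_mixed(logcpm, cohort, annotation = NULL)
  stats |>
    dplyr::rename(gene = "probe_id", expr_logfc = "effect") |>
    dplyr::select("gene", "expr_logfc", "se", "t_stat", "df", "p", "converged")
}

#' Link DMRs to gene expression
#'
#' For each gene-annotated DMR whose gene passes the expression filter, one
#' row pairing the DMR's mean methylation effect (M-value difference,
#' mood - control) with the gene's expression log2 fold change and p value.
#' A link is flagged significant iff `expr_p < 0.05` (pointwise, no
#' multiplicity correction).
#'
#' @param dmrs Annotated DMR tibble (see [call_dmrs()]).
#' @param gene_stats Output of [fit_gene_model()].
#' @param expressed Output of [filter_expressed()].
#' @param alpha Pointwise significance threshold, default 0.05.
#' @return A link tibble: `region_id`, `gene`, `meth_effect`, `expr_logfc`,
#'   `expr_p`, `promoter`, `significant`.
#' @export
link_dmrs <- function(dmrs, gene_stats, expressed, alpha = 0.05) {
  retained <- expressed$gene[expressed$retained]
  dmrs |>
    tibble::as_tibble() |>
    dplyr::filter(!is.na(.data$gene), .data$gene %in% retained) |>
    dplyr::inner_join(
      dplyr::select(gene_stats, "gene", "expr_logfc", expr_p = "p"),
      by = "gene") |>
    dplyr::transmute(
      .data$region_id, .data$gene,
      meth_effect = .data$mean_effect,
      .data$expr_logfc, .data$expr_p, .data$promoter,
      significant = .data$expr_p < alpha)
}

#' Correlate methylation and expression differences across links
#'
#' Pearson correlation between `meth_effect` and `expr_logfc` over the link
#' table (optionally promoter DMRs only), with the two-sided p value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param links A link tibble from [link_dmrs()].
#' @param promoter_only Restrict to promoter DMRs, default FALSE.
#' @return A list of class `link_correlation`: `r`, `n`, `p`, `degenerate`
#'   (TRUE when `|r| = 1`).
#' @export
correlate_links <- function(links, promoter_only = FALSE) {
  if (promoter_only) links <- dplyr::filter(links, .data$promoter)
  n <- nrow(links)
  if (n < 3) {
    abort_dmrpipe("need at least 3 link pairs for a correlation",
                  "dmrpipe_insufficient_pairs_error")
  }
  r <- cor(links$meth_effect, links$expr_logfc)
  structure(cor_test_r(r, n), class = "link_correlation")
}

# two-sided p for a Pearson r at sample size n (t transform, n - 2 df)
cor_test_r <- function(r, n) {
  if (abs(r) >= 1) {
    return(list(r = r, n = n, p = 0, degenerate = TRUE))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * pt(-abs(t), n - 2), degenerate = FALSE)
}

#' @export
print.link_correlation <- function(x, ...) {
  cat(sprintf("<link_correlation> r = %.4f (n = %d, two-sided p = %.4g)%s\n",
              x$r, x$n, x$p, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
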