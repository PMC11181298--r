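# Covariate adjustment, PCA, per-PC ANOVA variance partitioning, and MDS.

# design matrix for the residualization covariates (age numeric, sex binary)
covariate_design <- function(cohort, covariates) {
  stopifnot(all(covariates %in% c("age", "sex")))
  X <- matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  if ("age" %in% covariates) X <- cbind(X, age = cohort$age)
  if ("sex" %in% covariates) X <- cbind(X, sexmale = as.numeric(cohort$sex == "male"))
  if (qr(X)$rank < ncol(X)) {
    abort_dmrpipe("covariate design is rank deficient (e.g. single-sex cohort)",
                  "dmrpipe_design_error")
  }
  X
}

#' Residualize M-values on covariates
#'
#' Per probe, returns the residuals of an ordinary least squares fit of M on
#' an intercept plus the requested covariates (age numeric, sex binary).
#' With no covariates this is per-probe mean centering.
#'
#' @param m M-value matrix (probes x samples).
#' @param cohort Cohort tibble.
#' @param covariates Character subset of `c("age", "sex")`.
#' @return Residual matrix, same shape and dimnames.
#' @export
residualize <- function(m, cohort, covariates = c("age", "sex")) {
  m <- align_to_cohort(m, cohort, "M-value matrix")
  X <- covariate_design(cohort, covariates)
  qx <- qr(X)
  # residual per probe row: M - fitted, via one shared QR of the design
  res <- t(qr.resid(qx, t(m)))
  dimnames(res) <- dimnames(m)
  res
}

#' Top-K principal components of the sample space
#'
#' PCA of the probes x samples matrix with per-probe centering and no
#' scaling; scores are per sample, component variances are the squared
#' singular values over (n - 1).
#'
#' @param m M-value (or residualized) matrix, probes x samples.
#' @param K Number of components to keep (default 20, must be <= samples - 1).
#' @return A list of class `meth_pca`: `scores` (samples x K),
#'   `component_variances` (length K, descending), `total_variance`, `K`.
#' @export
pca_top <- function(m, K = 20) {
  n <- ncol(m)
  if (n < 2) abort_dmrpipe("PCA needs at least two samples", "dmrpipe_input_error")
  if (K > n - 1) {
    abort_dmrpipe(sprintf("K = %d exceeds samples - 1 = %d", K, n - 1),
                  "dmrpipe_parameter_error")
  }
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  structure(list(
    scores = pc$x[, seq_len(K), drop = FALSE],
    component_variances = vars[seq_len(K)],
    total_variance = sum(vars),
    K = K), class = "meth_pca")
}

#' Per-PC ANOVA variance fraction for one factor
#'
#' For each principal component, the fraction of the score variance explained
#' by the factor: one-way ANOVA `SS_between / SS_total` for categorical
#' factors, simple-regression R^2 for numeric factors (age).
#'
#' @param pca A [pca_top()] result.
#' @param cohort Cohort tibble.
#' @param factor Name of a cohort column (e.g. `"donor_id"`, `"region"`,
#'   `"mood_disorder"`, `"sex"`, `"age"`).
#' @return Numeric vector of per-PC fractions in \[0, 1\].
#' @export
per_pc_anova <- function(pca, cohort, factor) {
  f <- cohort[[factor]]
  if (is.null(f)) {
    abort_dmrpipe(sprintf("factor '%s' not found in cohort", factor),
                  "dmrpipe_input_error")
  }
  scores <- pca$scores
  stopifnot(nrow(scores) == nrow(cohort))
  if (is.numeric(f)) {
    if (sd(f) == 0) {
      abort_dmrpipe(sprintf("factor '%s' is constant", factor), "dmrpipe_degenerate_error")
    }
    return(apply(scores, 2, function(s) {
      ss_tot <- sum((s - mean(s))^2)
      if (ss_tot == 0) return(0)
      summary(lm(s ~ f))$r.squared
    }))
  }
  f <- factor(f)
  if (nlevels(f) < 2) {
    abort_dmrpipe(sprintf("factor '%s' has a single level", factor),
                  "dmrpipe_degenerate_error")
  }
  apply(scores, 2, function(s) {
    ss_tot <- sum((s - mean(s))^2)
    if (ss_tot == 0) return(0)
    group_means <- tapply(s, f, mean)
    ss_between <- sum(tabulate(f) * (group_means - mean(s))^2)
    ss_between / ss_tot
  })
}

#' Aggregate per-PC fractions into a percent of total variance
#'
#' `percent = 100 * sum_k fraction_k * var_k / sum_k var_k` over the retained
#' components.
#'
#' @param pca A [pca_top()] result.
#' @param per_pc Numeric vector of per-PC fractions, length `pca$K`.
#' @return A percentage in \[0, 100\].
#' @export
aggregate_fractions <- function(pca, per_pc) {
  stopifnot(length(per_pc) == pca$K)
  v <- pca$component_variances
  100 * sum(per_pc * v) / sum(v)
}

#' Variance partitioning of a methylation matrix
#'
#' Adjusts M-values for covariates, runs PCA, and attributes per-PC variance
#' to each requested factor by ANOVA, aggregated across the top K components
#' weighted by component variance.
#'
#' In `"separate"` mode (default) each factor is fitted alone (one-way), so
#' overlapping factors (donor subsumes sex and diagnosis) are reported side
#' by side and percentages need not sum to 100. In `"sequential"` mode a
#' joint linear model is fitted per PC in the given factor order and
#' sequential sums of squares are used; with the residual these sum to 1 per
#' PC.
#'
#' @param m M-value matrix (probes x samples).
#' @param cohort Cohort tibble.
#' @param factors Character vector of cohort columns to attribute.
#' @param adjust Covariates removed before PCA (subset of `c("age","sex")`;
#'   use `character()` for none).
#' @param K Number of PCs (default 20, capped at samples - 1).
#' @param mode `"separate"` or `"sequential"`.
#' @return A list of class `variance_partition`: `aggregated` (tibble factor,
#'   percent), `per_pc` (tibble pc, factor, fraction, component_variance),
#'   `pca`, `mode`, `adjust`.
#' @export
variance_partition <- function(m, cohort,
                               factors = c("donor_id", "region", "mood_disorder"),
                               adjust = c("age", "sex"),
                               K = 20, mode = c("separate", "sequential")) {
  mode <- match.arg(mode)
  cohort <- validate_cohort(cohort)
  m <- align_to_cohort(m, cohort, "M-value matrix")
  K <- min(K, ncol(m) - 1)
  adjusted <- if (length(adjust) > 0) residualize(m, cohort, adjust) else m
  pca <- pca_top(adjusted, K)

  if (mode == "separate") {
    per_pc <- purrr::map_dfr(factors, function(f) {
      tibble::tibble(pc = seq_len(K), factor = f,
                     fraction = per_pc_anova(pca, cohort, f))
    })
  } else {
    data <- cohort[factors]
    per_pc <- purrr::map_dfr(seq_len(K), function(k) {
      df <- data.frame(.score = pca$scores[, k], data, check.names = FALSE)
      fit <- lm(stats::reformulate(sprintf("`%s`", factors), ".score"), data = df)
      an <- anova(fit)
      ss <- an[["Sum Sq"]]
      tibble::tibble(pc = k, factor = rownames(an),
                     fraction = ss / sum(ss))
    }) |>
      dplyr::mutate(factor = ifelse(.data$factor == "Residuals", "residual",
                                    gsub("`", "", .data$factor)))
  }
  per_pc$component_variance <- pca$component_variances[per_pc$pc]

  aggregated <- per_pc |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(percent = 100 * sum(.data$fraction * .data$component_variance) /
                       sum(.data$component_variance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$percent))

  structure(list(aggregated = aggregated, per_pc = per_pc, pca = pca,
                 mode = mode, adjust = adjust),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> mode=%s, K=%d, adjusted for: %s\n",
              x$mode, x$pca$K,
              if (length(x$adjust)) paste(x$adjust, collapse = ", ") else "none"))
  print(x$aggregated)
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Euclidean distances on the `top_probes` most variable probes, embedded by
#' double-centering eigendecomposition.
#'
#' @param m M-value matrix (probes x samples).
#' @param n_dims Number of output dimensions (default 2).
#' @param top_probes Number of most-variable probes used (default 1000,
#'   capped at the probe count).
#' @return A tibble of class `meth_mds` with `sample_id` and `MDS1..MDSk`
#'   columns; attributes `eig` (eigenvalues) and `reduced` (TRUE when fewer
#'   positive eigenvalues than `n_dims` were available).
#' @export
classical_mds <- function(m, n_dims = 2, top_probes = 1000) {
  if (ncol(m) < 3) abort_dmrpipe("MDS needs at least 3 samples", "dmrpipe_input_error")
  rv <- apply(m, 1, var)
  keep <- order(rv, decreasing = TRUE)[seq_len(min(top_probes, nrow(m)))]
  d <- dist(t(m[keep, , drop = FALSE]))
  n_pos_max <- attr(d, "Size") - 1
  fit <- cmdscale(d, k = min(n_dims, n_pos_max), eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  reduced <- n_pos < n_dims
  coords <- fit$points[, seq_len(min(n_dims, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  out <- tibble::as_tibble(coords)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)), out)
  attr(out, "eig") <- fit$eig
  attr(out, "reduced") <- reduced
  class(out) <- c("meth_mds", class(out))
  out
}
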