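# Per-CpG association models: donor random-intercept REML across regions,
# ordinary least squares within a region, and genomic-inflation correction.

# ---------------------------------------------------------------------------
# Fast per-feature random-intercept REML.
#
# Model per feature: y = X beta + Z b + e, b ~ N(0, sigma_b^2 I),
# e ~ N(0, sigma^2 I), so V = sigma^2 (I + lambda Z Z'), lambda the variance
# ratio. The grouping (donor) and design are shared across features, so
# eigendecompose K = Z Z' = U D U' once; in the rotated basis V is diagonal
# and the profiled REML criterion
#   (n - p) log RSS_w(lambda) + sum log(1 + lambda d_i) + log|X' W X|
# is evaluated on a lambda grid for all features at once via sufficient
# statistics (D has few distinct values: the donor group sizes and 0), then
# refined per feature by parabolic interpolation in log lambda.
# ---------------------------------------------------------------------------
reml_mixed_matrix <- function(Y, X, group, coef_name,
                              grid = c(0, exp(seq(log(1e-3), log(1e3),
                                                  length.out = 91)))) {
  n <- ncol(Y)
  p <- ncol(X)
  m <- nrow(Y)
  group <- factor(group)
  q <- nlevels(group)
  Z <- stats::model.matrix(~ 0 + group)
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  d[d < 1e-8] <- 0

  Xt <- crossprod(U, X)
  Yt <- crossprod(U, t(Y))                 # n x m

  dr <- round(d, 6)
  ud <- sort(unique(dr))
  nk <- as.integer(table(factor(dr, levels = ud)))
  Sk <- lapply(ud, function(v) crossprod(Xt[dr == v, , drop = FALSE]))
  Bk <- lapply(ud, function(v) crossprod(Xt[dr == v, , drop = FALSE],
                                         Yt[dr == v, , drop = FALSE]))
  Ck <- vapply(ud, function(v) colSums(Yt[dr == v, , drop = FALSE]^2),
               numeric(m))
  # want distinct-eigenvalue groups in rows, features in columns
  Ck <- if (m == 1) matrix(Ck, ncol = 1) else t(Ck)

  nG <- length(grid)
  crit <- matrix(NA_real_, nG, m)
  rss_floor <- 1e-300
  eval_rss <- function(lam) {
    w <- 1 / (1 + lam * ud)
    A <- Reduce(`+`, Map(`*`, Sk, w))
    b <- Reduce(`+`, Map(`*`, Bk, w))
    cc <- as.vector(w %*% Ck)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, forwardsolve(t(R), b))
    rss <- pmax(cc - colSums(b * beta), rss_floor)
    list(rss = rss, beta = beta, R = R,
         logdetA = 2 * sum(log(diag(R))),
         logdetV = sum(nk * log(1 + lam * ud)))
  }
  for (g in seq_len(nG)) {
    e <- eval_rss(grid[g])
    if (is.null(e)) next
    crit[g, ] <- (n - p) * log(e$rss) + e$logdetV + e$logdetA
  }

  best <- apply(crit, 2, which.min)
  lam_hat <- grid[best]
  # parabolic refinement in log(lambda) for interior minima on the log grid
  lg <- log(grid[-1])
  h <- lg[2] - lg[1]
  interior <- which(best >= 3 & best <= nG - 1)
  if (length(interior) > 0) {
    j <- best[interior]
    c0 <- crit[cbind(j - 1, interior)]
    c1 <- crit[cbind(j, interior)]
    c2 <- crit[cbind(j + 1, interior)]
    denom <- c0 - 2 * c1 + c2
    shift <- ifelse(denom > 0, 0.5 * h * (c0 - c2) / denom, 0)
    shift <- pmax(pmin(shift, h), -h)
    lam_hat[interior] <- exp(lg[j - 1] + shift)
  }

  effect <- se <- rss_out <- rep(NA_real_, m)
  idx_coef <- match(coef_name, colnames(X))
  stopifnot(!is.na(idx_coef))
  for (lam in unique(lam_hat)) {
    jj <- which(lam_hat == lam)
    w <- 1 / (1 + lam * ud)
    A <- Reduce(`+`, Map(`*`, Sk, w))
    b <- Reduce(`+`, Map(`*`, Bk, w))[, jj, drop = FALSE]
    cc <- as.vector(w %*% Ck[, jj, drop = FALSE])
    Ainv <- solve(A)
    beta <- Ainv %*% b
    rss <- pmax(cc - colSums(b * beta), 0)
    s2 <- rss / (n - p)
    effect[jj] <- beta[idx_coef, ]
    se[jj] <- sqrt(s2 * Ainv[idx_coef, idx_coef])
    rss_out[jj] <- rss
  }

  df <- n - p - q + 1
  degenerate <- !is.finite(se) | se <= 0 | rss_out < 1e-10
  t_stat <- ifelse(degenerate, NA_real_, effect / se)
  pval <- 2 * pt(-abs(t_stat), df)
  tibble::tibble(effect = ifelse(is.finite(effect), effect, NA_real_),
                 se = ifelse(degenerate, NA_real_, se),
                 t_stat = t_stat, df = df, p = pval,
                 variance_ratio = lam_hat, converged = !degenerate)
}

# fixed-effect design shared by the mixed and per-region models
mood_design <- function(cohort, include_region = TRUE) {
  X <- cbind(`(Intercept)` = 1,
             mood = as.numeric(cohort$mood_disorder),
             age = cohort$age,
             sexmale = as.numeric(cohort$sex == "male"))
  if (include_region) {
    regions <- sort(unique(cohort$region))
    if (length(regions) > 1) {
      for (r in regions[-1]) {
        X <- cbind(X, as.numeric(cohort$region == r))
        colnames(X)[ncol(X)] <- paste0("region", r)
      }
    }
  }
  if (qr(X)$rank < ncol(X)) {
    abort_dmrpipe("model design is rank deficient", "dmrpipe_design_error")
  }
  X
}

attach_annotation <- function(stats, probe_ids, annotation) {
  out <- dplyr::bind_cols(tibble::tibble(probe_id = probe_ids), stats)
  if (!is.null(annotation)) {
    out <- out |>
      dplyr::left_join(dplyr::select(annotation, "probe_id", "chrom", "pos"),
                       by = "probe_id") |>
      dplyr::relocate("probe_id", "chrom", "pos") |>
      dplyr::arrange(.data$chrom, .data$pos)
  }
  out
}

#' Per-CpG mixed model (donor random intercept)
#'
#' Fits, per probe, `M ~ mood_disorder + age + sex + region + (1 | donor)` by
#' profiled REML and reports the mood-disorder coefficient (M-value
#' difference, mood - control) with its standard error, t statistic and
#' two-sided p value. Degrees of freedom use the residual approximation
#' `n - p - n_donors + 1`.
#'
#' @param m M-value matrix (probes x samples).
#' @param cohort Cohort tibble (repeated donors allowed).
#' @param annotation Optional probe annotation; when given, `chrom`/`pos` are
#'   attached and rows sorted by position.
#' @return A CpG statistics tibble: `probe_id` (+ `chrom`, `pos`), `effect`,
#'   `se`, `t_stat`, `df`, `p`, `p_adjusted` (initially equal to `p`),
#'   `variance_ratio` (donor/residual variance ratio), `converged`. The
#'   attribute `n_failed` counts probes with degenerate fits.
#' @export
fit_cpg_mixed <- function(m, cohort, annotation = NULL) {
  cohort <- validate_cohort(cohort)
  m <- align_to_cohort(m, cohort, "M-value matrix")
  donors <- dplyr::distinct(cohort, .data$donor_id, .data$mood_disorder)
  if (length(unique(donors$mood_disorder)) < 2) {
    abort_dmrpipe("both diagnostic groups must be present", "dmrpipe_design_error")
  }
  if (any(table(donors$mood_disorder) < 2)) {
    abort_dmrpipe("need at least 2 donors per diagnostic group", "dmrpipe_design_error")
  }
  X <- mood_design(cohort, include_region = TRUE)
  stats <- reml_mixed_matrix(m, X, cohort$donor_id, "mood")
  stats$p_adjusted <- stats$p
  out <- attach_annotation(stats, rownames(m), annotation)
  attr(out, "n_failed") <- sum(!stats$converged)
  attr(out, "model") <- "mixed"
  out
}

#' Per-CpG fixed-effect model for a single region
#'
#' Ordinary least squares `M ~ mood_disorder + age + sex` per probe, for a
#' cohort restricted to one brain region (one sample per donor). Two-sided p
#' from t with `n - 4` degrees of freedom.
#'
#' @inheritParams fit_cpg_mixed
#' @return A CpG statistics tibble as in [fit_cpg_mixed()] (without
#'   `variance_ratio`).
#' @export
fit_cpg_fixed <- function(m, cohort, annotation = NULL) {
  cohort <- validate_cohort(cohort)
  if (length(unique(cohort$region)) != 1) {
    abort_dmrpipe("fixed-effect model expects a single-region cohort",
                  "dmrpipe_design_error")
  }
  if (anyDuplicated(cohort$donor_id)) {
    abort_dmrpipe("fixed-effect model expects one sample per donor",
                  "dmrpipe_design_error")
  }
  n <- nrow(cohort)
  if (n <= 4) {
    abort_dmrpipe("insufficient samples for the fixed-effect model (need n > 4)",
                  "dmrpipe_insufficient_sample_error")
  }
  m <- align_to_cohort(m, cohort, "M-value matrix")
  X <- mood_design(cohort, include_region = FALSE)
  p <- ncol(X)
  qx <- qr(X)
  Yt <- t(m)
  beta <- qr.coef(qx, Yt)
  res <- qr.resid(qx, Yt)
  rss <- colSums(res^2)
  df <- n - p
  s2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * xtx_inv[2, 2])
  effect <- unname(beta["mood", ])
  se <- unname(se)
  # a perfect (zero-residual) fit still has a well-defined coefficient, but
  # no usable t statistic
  degenerate <- !is.finite(se) | se <= 0 | rss < 1e-10
  t_stat <- ifelse(degenerate, NA_real_, effect / se)
  pval <- 2 * pt(-abs(t_stat), df)
  stats <- tibble::tibble(effect = ifelse(is.finite(effect), effect, NA_real_),
                          se = ifelse(degenerate, NA_real_, se),
                          t_stat = t_stat, df = df, p = pval,
                          converged = !degenerate)
  stats$p_adjusted <- stats$p
  out <- attach_annotation(stats, rownames(m), annotation)
  attr(out, "n_failed") <- sum(degenerate)
  attr(out, "model") <- "fixed"
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`; values
#' above 1 indicate test-statistic inflation.
#'
#' @param p Numeric vector of p values in (0, 1\].
#' @return A list of class `inflation_estimate`: `lambda`, `n_tests`,
#'   `reliable` (FALSE with a warning when fewer than 100 tests).
#' @export
genomic_lambda <- function(p) {
  p <- p[is.finite(p)]
  reliable <- length(p) >= 100
  if (!reliable) {
    rlang::warn("fewer than 100 p-values: inflation estimate is unreliable")
  }
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  structure(list(lambda = median(chisq) / qchisq(0.5, df = 1),
                 n_tests = length(p), reliable = reliable),
            class = "inflation_estimate")
}

#' @export
print.inflation_estimate <- function(x, ...) {
  cat(sprintf("<inflation_estimate> lambda = %.4f over %d tests%s\n",
              x$lambda, x$n_tests, if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

#' Genomic-inflation correction of per-CpG p values
#'
#' Correction is applied only when `lambda > 1` (deflation is never
#' "corrected" upward). `multiply_p` is the literal rule
#' `p_adjusted = min(1, p * lambda)`; `genomic_control` is the standard rule
#' that divides the implied 1-df chi-square statistic by lambda.
#'
#' @param stats CpG statistics tibble with a `p` column.
#' @param lam An [genomic_lambda()] estimate (or a bare number).
#' @param mode `"multiply_p"` (default) or `"genomic_control"`.
#' @return `stats` with `p_adjusted` filled; attributes `lambda` and
#'   `inflation_applied`.
#' @export
inflation_adjust <- function(stats, lam, mode = c("multiply_p", "genomic_control")) {
  mode <- match.arg(mode)
  lambda <- if (inherits(lam, "inflation_estimate")) lam$lambda else lam
  stopifnot(is.finite(lambda), lambda > 0)
  apply_it <- lambda > 1
  if (!apply_it) {
    stats$p_adjusted <- stats$p
  } else if (mode == "multiply_p") {
    stats$p_adjusted <- pmin(1, stats$p * lambda)
  } else {
    chisq <- qchisq(stats$p, df = 1, lower.tail = FALSE)
    stats$p_adjusted <- pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
  }
  attr(stats, "lambda") <- lambda
  attr(stats, "inflation_applied") <- apply_it
  stats
}
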