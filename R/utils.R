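# Internal helpers shared across modules.

#' Logit (base 2) and its inverse
#'
#' M-values are the base-2 logit of methylation beta values,
#' `M = log2(beta / (1 - beta))`; the inverse maps the real line back to (0,1).
#'
#' @param beta,m Numeric vectors or matrices.
#' @return Numeric object of the same shape.
#' @keywords internal
#' @noRd
logit2 <- function(beta) log2(beta / (1 - beta))

#' @noRd
inv_logit2 <- function(m) {
  # 2^m / (1 + 2^m), computed stably for large |m|
  stats::plogis(m * log(2))
}

# stop with a classed condition so callers/tests can match on class
abort_dmrpipe <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "dmrpipe_error"), ...)
}

check_matrix_labels <- function(x, what) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort_dmrpipe(sprintf("%s must have row and column names", what),
                  "dmrpipe_format_error")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort_dmrpipe(sprintf("%s has duplicated row or column names", what),
                  "dmrpipe_format_error")
  }
  invisible(x)
}

# Samples-in-columns matrix aligned to a cohort: reorder columns to the
# cohort's sample_id, erroring on any mismatch.
align_to_cohort <- function(x, cohort, what = "matrix") {
  missing <- setdiff(cohort$sample_id, colnames(x))
  if (length(missing) > 0) {
    abort_dmrpipe(
      sprintf("%s is missing samples present in the cohort: %s",
              what, paste(utils::head(missing, 5), collapse = ", ")),
      "dmrpipe_consistency_error")
  }
  x[, cohort$sample_id, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
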