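# Sample- and probe-level QC, and the beta -> M transformation.

#' Per-sample detection call rates
#'
#' The call rate of a sample is the fraction of probes with detection
#' p strictly below `alpha` (a probe whose p equals `alpha` counts as NOT
#' detected). Samples below `min_call_rate` are flagged.
#'
#' @param detp Detection p-value matrix (probes x samples).
#' @param alpha Detection threshold, default `5e-5`.
#' @param min_call_rate Minimum acceptable call rate, default 0.97.
#' @return A tibble: `sample_id`, `call_rate`, `flagged`.
#' @export
detection_call_rate <- function(detp, alpha = 5e-5, min_call_rate = 0.97) {
  if (length(detp) == 0) {
    abort_dmrpipe("empty detection p-value matrix", "dmrpipe_input_error")
  }
  stopifnot(alpha > 0, alpha < 1)
  rate <- colMeans(detp < alpha)
  tibble::tibble(
    sample_id = colnames(detp),
    call_rate = unname(rate),
    flagged = unname(rate < min_call_rate))
}

#' Beta to M-value transformation
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[epsilon, 1 - epsilon]` so that boundary values stay finite.
#'
#' @param beta Beta-value matrix in \[0, 1\].
#' @param epsilon Clipping constant in (0, 0.01\], default `1e-6`.
#' @return An M-value matrix of the same shape, with attributes `kind = "m"`
#'   and `epsilon`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(epsilon > 0, epsilon <= 0.01)
  clipped <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(clipped / (1 - clipped))
  attributes(m) <- attributes(beta)[c("dim", "dimnames")]
  attr(m, "kind") <- "m"
  attr(m, "epsilon") <- epsilon
  m
}

#' Inverse of [beta_to_m()]
#' @param m M-value matrix.
#' @return Beta-value matrix in (0, 1).
#' @export
m_to_beta <- function(m) {
  beta <- inv_logit2(m)
  attributes(beta) <- attributes(m)[c("dim", "dimnames")]
  attr(beta, "kind") <- "beta"
  beta
}

#' Infer sample sex from sex-chromosome methylation
#'
#' Samples are summarised by their mean sex-chromosome M-value and split by
#' 1-D two-means clustering. Each cluster is labeled with the majority
#' reported sex of its members; samples whose reported sex disagrees with
#' their cluster label are flagged. If the two cluster centers (or all
#' summaries) coincide the clustering is degenerate and every sample is
#' flagged `"indeterminate"`.
#'
#' @param m M-value matrix (probes x samples).
#' @param annotation Probe annotation tibble.
#' @param cohort Cohort tibble with reported `sex`.
#' @return A tibble: `sample_id`, `reported_sex`, `inferred_sex`, `flagged`.
#' @export
infer_sex <- function(m, annotation, cohort) {
  sex_probes <- annotation$probe_id[annotation$probe_class == "sex_chromosome"]
  sex_probes <- intersect(sex_probes, rownames(m))
  if (length(sex_probes) == 0) {
    abort_dmrpipe("no sex-chromosome probes available", "dmrpipe_capability_error")
  }
  m <- align_to_cohort(m, cohort, "M-value matrix")
  if (ncol(m) < 2) {
    abort_dmrpipe("sex inference needs at least two samples", "dmrpipe_input_error")
  }
  summary_m <- colMeans(m[sex_probes, , drop = FALSE])

  # deterministic 1-D two-means: centers initialised at min/max, iterate
  centers <- range(summary_m)
  if (diff(centers) < 1e-12) {
    return(tibble::tibble(
      sample_id = cohort$sample_id,
      reported_sex = cohort$sex,
      inferred_sex = "indeterminate",
      flagged = TRUE))
  }
  for (i in 1:100) {
    cl <- ifelse(abs(summary_m - centers[1]) <= abs(summary_m - centers[2]), 1L, 2L)
    new_centers <- c(mean(summary_m[cl == 1]), mean(summary_m[cl == 2]))
    if (isTRUE(all.equal(new_centers, centers))) break
    centers <- new_centers
  }
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  lab <- vapply(1:2, function(k) majority(cohort$sex[cl == k]), character(1))
  if (lab[1] == lab[2]) {
    inferred <- rep("indeterminate", length(cl))
  } else {
    inferred <- lab[cl]
  }
  tibble::tibble(
    sample_id = cohort$sample_id,
    reported_sex = cohort$sex,
    inferred_sex = inferred,
    flagged = inferred != cohort$sex)
}

#' SNP-fingerprint concordance check
#'
#' Pairwise sample distance = mean absolute beta difference over fingerprint
#' probes; samples are clustered by single linkage at `threshold`. Samples of
#' the same donor are expected to land in the same cluster, and no cluster
#' should span donors; violations are flagged.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param annotation Probe annotation tibble (needs >= 10 `snp_fingerprint`
#'   probes).
#' @param cohort Cohort tibble.
#' @param threshold Single-linkage cut height, default 0.1.
#' @return A list: `distance` (sample x sample matrix), `clusters` (tibble
#'   sample_id, donor_id, cluster), `concordant` (logical), `flagged`
#'   (tibble sample_id, reason).
#' @export
fingerprint_concordance <- function(beta, annotation, cohort, threshold = 0.1) {
  fp <- annotation$probe_id[annotation$probe_class == "snp_fingerprint"]
  fp <- intersect(fp, rownames(beta))
  if (length(fp) < 10) {
    abort_dmrpipe("fewer than 10 SNP-fingerprint probes available",
                  "dmrpipe_capability_error")
  }
  beta <- align_to_cohort(beta, cohort, "beta matrix")
  x <- t(beta[fp, , drop = FALSE])
  d <- as.matrix(dist(x, method = "manhattan")) / length(fp)

  hc <- stats::hclust(stats::as.dist(d), method = "single")
  cl <- stats::cutree(hc, h = threshold)
  clusters <- tibble::tibble(
    sample_id = cohort$sample_id,
    donor_id = cohort$donor_id,
    cluster = unname(cl[cohort$sample_id]))

  by_donor <- clusters |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarise(n_clusters = dplyr::n_distinct(.data$cluster))
  by_cluster <- clusters |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_donors = dplyr::n_distinct(.data$donor_id))

  flagged <- dplyr::bind_rows(
    clusters |>
      dplyr::filter(.data$donor_id %in% by_donor$donor_id[by_donor$n_clusters > 1]) |>
      dplyr::transmute(.data$sample_id, reason = "donor split across fingerprint clusters"),
    clusters |>
      dplyr::filter(.data$cluster %in% by_cluster$cluster[by_cluster$n_donors > 1]) |>
      dplyr::transmute(.data$sample_id, reason = "fingerprint cluster spans donors")) |>
    dplyr::distinct()

  list(distance = d, clusters = clusters,
       concordant = nrow(flagged) == 0, flagged = flagged)
}

#' RNA-seq sample QC
#'
#' A sample fails if aligned reads < 10 million, OR ribosomal fraction > 20%,
#' OR coding fraction < 10% (strict inequalities).
#'
#' @param metrics Tibble with `sample_id`, `aligned_reads`,
#'   `ribosomal_fraction`, `coding_fraction`.
#' @return A tibble: `sample_id`, `pass`, `reasons` (character, `;`-joined).
#' @export
rna_sample_qc <- function(metrics) {
  required <- c("sample_id", "aligned_reads", "ribosomal_fraction", "coding_fraction")
  missing <- setdiff(required, names(metrics))
  if (length(missing) > 0) {
    abort_dmrpipe(sprintf("RNA QC metrics missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "dmrpipe_input_error")
  }
  if (anyNA(metrics[required])) {
    abort_dmrpipe("RNA QC metrics contain missing values", "dmrpipe_input_error")
  }
  metrics |>
    tibble::as_tibble() |>
    dplyr::rowwise() |>
    dplyr::mutate(
      reasons = paste(c(
        if (.data$aligned_reads < 1e7) "aligned reads < 10M",
        if (.data$ribosomal_fraction > 0.20) "ribosomal fraction > 20%",
        if (.data$coding_fraction < 0.10) "coding fraction < 10%"),
        collapse = ";")) |>
    dplyr::ungroup() |>
    dplyr::mutate(pass = .data$reasons == "") |>
    dplyr::select("sample_id", "pass", "reasons")
}

#' Combined methylation QC report
#'
#' Runs [detection_call_rate()], [infer_sex()] and
#' [fingerprint_concordance()] and collects all flags.
#'
#' @inheritParams fingerprint_concordance
#' @param detp Detection p-value matrix.
#' @param alpha,min_call_rate See [detection_call_rate()].
#' @return A list of class `qc_report`: `call_rate`, `sex`, `fingerprint`,
#'   `flags` (tibble sample_id, reason).
#' @export
qc_report <- function(beta, detp, annotation, cohort,
                      alpha = 5e-5, min_call_rate = 0.97, threshold = 0.1) {
  cr <- detection_call_rate(detp, alpha, min_call_rate)
  sex <- infer_sex(beta_to_m(beta), annotation, cohort)
  fp <- fingerprint_concordance(beta, annotation, cohort, threshold)
  flags <- dplyr::bind_rows(
    cr |> dplyr::filter(.data$flagged) |>
      dplyr::transmute(.data$sample_id,
                       reason = sprintf("call rate %.4f below %.2f",
                                        .data$call_rate, min_call_rate)),
    sex |> dplyr::filter(.data$flagged) |>
      dplyr::transmute(.data$sample_id,
                       reason = sprintf("reported sex %s, inferred %s",
                                        .data$reported_sex, .data$inferred_sex)),
    fp$flagged)
  structure(list(call_rate = cr, sex = sex, fingerprint = fp, flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples, %d flag(s)\n",
              nrow(x$call_rate), nrow(x$flags)))
  cat(sprintf("  call rate: min %.4f  median %.4f\n",
              min(x$call_rate$call_rate), median(x$call_rate$call_rate)))
  cat(sprintf("  sex mismatches: %d; fingerprint concordant: %s\n",
              sum(x$sex$flagged), x$fingerprint$concordant))
  if (nrow(x$flags) > 0) print(x$flags, n = 10)
  invisible(x)
}
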