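# Readers/writers and validators for the tabular formats the pipeline touches.
#
# Conventions: all matrices are TSV with the probe/gene id in the first column
# and one column per sample; internal probe coordinates are 1-based CpG
# positions; BED output is 0-based half-open.

DIAGNOSIS_LEVELS <- c("control", "MDD", "bipolar", "schizophrenia")
MOOD_DIAGNOSES <- c("MDD", "bipolar")
REGION_LEVELS <- c("MFG", "STG", "SVZ", "THA")
SEX_LEVELS <- c("female", "male")
PROBE_CLASSES <- c("autosomal", "sex_chromosome", "snp_fingerprint")

#' Validate a cohort table
#'
#' Checks the per-sample metadata table against the cohort invariants: unique
#' sample ids, closed vocabularies for sex/diagnosis/region, nonnegative ages,
#' a consistent (age, sex, diagnosis) triple per donor, and a `mood_disorder`
#' flag equal to `diagnosis %in% c("MDD", "bipolar")` (added if absent).
#'
#' @param cohort A data frame with columns `sample_id`, `donor_id`, `age`,
#'   `sex`, `diagnosis`, `region` and optionally `postmortem_delay`.
#' @return The validated cohort as a tibble, with `mood_disorder` derived.
#' @export
validate_cohort <- function(cohort) {
  required <- c("sample_id", "donor_id", "age", "sex", "diagnosis", "region")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort_dmrpipe(sprintf("sample sheet is missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "dmrpipe_format_error")
  }
  cohort <- tibble::as_tibble(cohort)
  if (anyDuplicated(cohort$sample_id)) {
    abort_dmrpipe("sample_id values must be unique", "dmrpipe_consistency_error")
  }
  if (any(!cohort$sex %in% SEX_LEVELS)) {
    abort_dmrpipe(sprintf("unknown sex label(s): %s",
                          paste(setdiff(unique(cohort$sex), SEX_LEVELS), collapse = ", ")),
                  "dmrpipe_format_error")
  }
  if (any(!cohort$diagnosis %in% DIAGNOSIS_LEVELS)) {
    abort_dmrpipe(sprintf("unknown diagnosis label(s): %s (vocabulary is closed: %s)",
                          paste(setdiff(unique(cohort$diagnosis), DIAGNOSIS_LEVELS), collapse = ", "),
                          paste(DIAGNOSIS_LEVELS, collapse = ", ")),
                  "dmrpipe_format_error")
  }
  if (any(!cohort$region %in% REGION_LEVELS)) {
    abort_dmrpipe(sprintf("unknown region label(s): %s",
                          paste(setdiff(unique(cohort$region), REGION_LEVELS), collapse = ", ")),
                  "dmrpipe_format_error")
  }
  if (any(!is.finite(cohort$age)) || any(cohort$age < 0)) {
    abort_dmrpipe("age must be nonnegative and finite", "dmrpipe_format_error")
  }
  bad_donor <- cohort |>
    dplyr::distinct(.data$donor_id, .data$age, .data$sex, .data$diagnosis) |>
    dplyr::count(.data$donor_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_donor) > 0) {
    abort_dmrpipe(sprintf(
      "donor(s) with inconsistent age/sex/diagnosis across rows: %s",
      paste(bad_donor$donor_id, collapse = ", ")),
      "dmrpipe_consistency_error")
  }
  derived <- cohort$diagnosis %in% MOOD_DIAGNOSES
  if ("mood_disorder" %in% names(cohort)) {
    if (!identical(as.logical(cohort$mood_disorder), derived)) {
      abort_dmrpipe("mood_disorder column disagrees with diagnosis",
                    "dmrpipe_consistency_error")
    }
  }
  cohort$mood_disorder <- derived
  cohort
}

#' Read a sample sheet
#'
#' Reads a TSV sample sheet (one row per sample) and validates it with
#' [validate_cohort()]. The `mood_disorder` column is derived from diagnosis.
#'
#' @param path Path to a tab-separated file with a header.
#' @return A tibble of sample records.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  validate_cohort(sheet)
}

#' Write a sample sheet
#' @param cohort Cohort tibble (see [validate_cohort()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  readr::write_tsv(validate_cohort(cohort), path, progress = FALSE)
  invisible(path)
}

#' Read a probes/genes x samples matrix
#'
#' First column is the probe or gene id; remaining columns are samples. Values
#' are validated against the declared kind: beta and detection p values must
#' lie in \[0, 1\] and counts must be nonnegative integers. Missing values are
#' rejected.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"beta"`, `"detection_p"`, `"counts"`, `"m"` (M-values,
#'   unconstrained but finite).
#' @return A numeric matrix with row and column names, with an attribute
#'   `kind`.
#' @export
read_matrix <- function(path, kind = c("beta", "detection_p", "counts", "m")) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  validate_matrix(values, kind, context = path)
}

#' Validate a numeric methylation/count matrix
#' @param values Numeric matrix with dimnames.
#' @param kind As in [read_matrix()].
#' @param context Label used in error messages (e.g. a file path).
#' @return The matrix (integer storage for counts), with `kind` attribute.
#' @export
validate_matrix <- function(values, kind = c("beta", "detection_p", "counts", "m"),
                            context = "matrix") {
  kind <- match.arg(kind)
  check_matrix_labels(values, context)
  if (anyNA(values) || any(!is.finite(values))) {
    abort_dmrpipe(sprintf("%s: missing or non-finite values are not allowed", context),
                  "dmrpipe_format_error")
  }
  if (kind %in% c("beta", "detection_p")) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort_dmrpipe(sprintf("%s: value %g outside [0,1] at probe %s",
                            context, values[bad[1, , drop = FALSE]],
                            rownames(values)[bad[1, 1]]),
                    "dmrpipe_range_error")
    }
  }
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      bad <- which(values < 0 | values != round(values), arr.ind = TRUE)
      abort_dmrpipe(sprintf("%s: counts must be nonnegative integers (offending gene %s)",
                            context, rownames(values)[bad[1, 1]]),
                    "dmrpipe_format_error")
    }
    storage.mode(values) <- "integer"
  }
  attr(values, "kind") <- kind
  values
}

#' Write a matrix as TSV (id in the first column)
#' @param values Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the first column (default `"id"`).
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(values, path, id_col = "id", header = NULL) {
  check_matrix_labels(values, path)
  tab <- tibble::as_tibble(values, rownames = id_col)
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Validate probe annotation
#'
#' @param annotation Data frame with columns `probe_id`, `chrom`, `pos`,
#'   `probe_class`, and optionally `gene` (string, may be `NA`) and `promoter`
#'   (logical).
#' @return Validated tibble sorted by `(chrom, pos)`, with `gene`/`promoter`
#'   filled with defaults when absent.
#' @export
validate_probe_annotation <- function(annotation) {
  required <- c("probe_id", "chrom", "pos", "probe_class")
  missing <- setdiff(required, names(annotation))
  if (length(missing) > 0) {
    abort_dmrpipe(sprintf("probe annotation is missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "dmrpipe_format_error")
  }
  annotation <- tibble::as_tibble(annotation)
  if (anyDuplicated(annotation$probe_id)) {
    abort_dmrpipe("probe_id values must be unique", "dmrpipe_consistency_error")
  }
  if (any(!annotation$probe_class %in% PROBE_CLASSES)) {
    abort_dmrpipe("unknown probe_class value", "dmrpipe_format_error")
  }
  if (any(annotation$pos < 1 | annotation$pos != round(annotation$pos))) {
    abort_dmrpipe("pos must be a 1-based integer coordinate", "dmrpipe_format_error")
  }
  if (!"gene" %in% names(annotation)) annotation$gene <- NA_character_
  if (!"promoter" %in% names(annotation)) annotation$promoter <- FALSE
  annotation$promoter[is.na(annotation$promoter)] <- FALSE
  fp <- annotation$probe_class == "snp_fingerprint"
  annotation$gene[fp] <- NA_character_
  annotation$promoter[fp] <- FALSE
  dup <- annotation |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_dmrpipe("duplicate (chrom, pos) in probe annotation",
                  "dmrpipe_consistency_error")
  }
  dplyr::arrange(annotation, .data$chrom, .data$pos)
}

#' Read probe annotation from TSV
#' @param path Path to a TSV file with the columns of [validate_probe_annotation()].
#' @return A validated annotation tibble.
#' @export
read_probe_annotation <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_probe_annotation(tab)
}

#' Write probe annotation as TSV
#' @inheritParams write_sample_sheet
#' @param annotation Annotation tibble.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  readr::write_tsv(validate_probe_annotation(annotation), path, progress = FALSE)
  invisible(path)
}

#' Write DMRs as BED6+
#'
#' Emits one line per region: chrom, 0-based half-open start/end, name (gene
#' symbol if annotated, else region id), score `-10*log10(p_sidak)` capped at
#' 1000, strand `"."`, then `n_probes`, `p_region`, `p_sidak`. Internal
#' coordinates are 1-based inclusive, so `start_bed = start - 1`,
#' `end_bed = end`.
#'
#' @param dmrs A DMR table (see [call_dmrs()]), sorted by `(chrom, start)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) > 0) {
    o <- order(dmrs$chrom, dmrs$start)
    if (!identical(o, seq_len(nrow(dmrs)))) {
      abort_dmrpipe("DMR table must be sorted by (chrom, start) before BED export",
                    "dmrpipe_ordering_error")
    }
  }
  score <- pmin(1000, -10 * log10(pmax(dmrs$p_sidak, 1e-100)))
  name <- dplyr::coalesce(dmrs$gene, dmrs$region_id)
  name[name == ""] <- dmrs$region_id[name == ""]
  bed <- tibble::tibble(
    chrom = dmrs$chrom,
    start = as.integer(dmrs$start - 1L),
    end = as.integer(dmrs$end),
    name = name,
    score = round(score, 4),
    strand = ".",
    n_probes = dmrs$n_probes,
    p_region = dmrs$p_region,
    p_sidak = dmrs$p_sidak
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6+ DMR file written by [write_dmr_bed()]
#'
#' Converts BED half-open 0-based coordinates back to the internal 1-based
#' inclusive convention.
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive), `name`,
#'   `score`, `n_probes`, `p_region`, `p_sidak`.
#' @export
read_dmr_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "n_probes", "p_region", "p_sidak"),
    show_col_types = FALSE, progress = FALSE)
  bed |>
    dplyr::mutate(start = .data$start + 1L) |>
    dplyr::select(-"strand")
}
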