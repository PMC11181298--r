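# End-to-end orchestration: simulate -> qc -> varpart -> dmtest -> dmr ->
# link, with a YAML-style config, TSV artifacts and a checksum manifest.

#' Pipeline configuration
#'
#' Builds the full parameter set with module defaults; unknown keys are
#' rejected. `simulate` entries are passed to [sim_config()].
#'
#' @param ... Named overrides, possibly nested lists for `simulate`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = list(),                 # sim_config() overrides
    qc = list(alpha = 5e-5, min_call_rate = 0.97, fingerprint_threshold = 0.1),
    varpart = list(factors = c("donor_id", "region", "mood_disorder"),
                   adjust = c("age", "sex"), k = 20, mode = "separate"),
    dmtest = list(model = "mixed", inflation = "multiply_p"),
    dmr = list(seed_p = 0.05, max_gap = 500, min_probes = 3, alpha = 0.05,
               max_dist = 1000, bin_width = 100),
    link = list(threshold = 1, promoter_only = FALSE))
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort_dmrpipe(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                  "dmrpipe_config_error")
  }
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      sub_unknown <- if (key == "simulate") character(0) else
        setdiff(names(overrides[[key]]), names(defaults[[key]]))
      if (length(sub_unknown) > 0) {
        abort_dmrpipe(sprintf("unknown config key(s) under %s: %s", key,
                              paste(sub_unknown, collapse = ", ")),
                      "dmrpipe_config_error")
      }
      defaults[[key]] <- modifyList(defaults[[key]], overrides[[key]])
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline config from a YAML file
#' @param path Path to a YAML key/value file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

pipeline_header <- function(config) {
  hash <- digest_config(config)
  c(sprintf("dmrpipe %s", as.character(utils::packageVersion("dmrpipe"))),
    sprintf("config_hash %s", hash),
    sprintf("seed %d", config$seed))
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(rapply(unclass(config), unclass, how = "replace"), tmp,
          version = 2, compress = FALSE)
  # strip the serialization header (carries R version) before hashing
  unname(tools::md5sum(tmp))
}

write_table_artifact <- function(tab, path, header) {
  writeLines(paste0("# ", header), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  path
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes, in order: simulation, methylation and RNA QC, variance
#' partitioning plus MDS, the per-CpG model with inflation correction, DMR
#' calling, and expression linkage. All artifacts are written under
#' `out_dir` as TSV (with `#` header lines recording the package version,
#' config hash and seed) plus a BED file of the DMRs, and a manifest of
#' md5 checksums.
#'
#' @param config A [pipeline_config()] (or a list of overrides).
#' @param out_dir Output directory (created if needed).
#' @return A list of class `pipeline_run`: `manifest` (tibble artifact,
#'   path, md5), `results` (in-memory stage outputs), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("dmrpipe_")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- pipeline_header(config)
  message("[dmrpipe] stage simulate")
  sim_overrides <- modifyList(config$simulate, list(seed = config$seed))
  scfg <- do.call(sim_config, sim_overrides)
  data <- simulate_dataset(scfg)

  message("[dmrpipe] stage qc")
  qc <- qc_report(data$beta, data$detp, data$annotation, data$cohort,
                  alpha = config$qc$alpha,
                  min_call_rate = config$qc$min_call_rate,
                  threshold = config$qc$fingerprint_threshold)
  rna_qc <- rna_sample_qc(data$rna_qc)

  message("[dmrpipe] stage varpart")
  m <- beta_to_m(data$beta)
  auto <- data$annotation$probe_id[data$annotation$probe_class == "autosomal"]
  vp <- variance_partition(m[auto, , drop = FALSE], data$cohort,
                           factors = config$varpart$factors,
                           adjust = config$varpart$adjust,
                           K = config$varpart$k, mode = config$varpart$mode)
  mds <- classical_mds(m[auto, , drop = FALSE])

  message("[dmrpipe] stage dmtest")
  stats <- if (config$dmtest$model == "mixed") {
    fit_cpg_mixed(m[auto, , drop = FALSE], data$cohort, data$annotation)
  } else {
    fit_cpg_fixed(m[auto, , drop = FALSE], data$cohort, data$annotation)
  }
  lam <- genomic_lambda(stats$p)
  if (config$dmtest$inflation != "none") {
    stats <- inflation_adjust(stats, lam, mode = config$dmtest$inflation)
  }

  message("[dmrpipe] stage dmr")
  dmrs <- call_dmrs(stats, data$annotation,
                    seed_p = config$dmr$seed_p, max_gap = config$dmr$max_gap,
                    min_probes = config$dmr$min_probes, alpha = config$dmr$alpha,
                    max_dist = config$dmr$max_dist, bin_width = config$dmr$bin_width)

  message("[dmrpipe] stage link")
  keep <- rna_qc$sample_id[rna_qc$pass]
  cohort_rna <- data$cohort[data$cohort$sample_id %in% keep, ]
  logcpm <- log_cpm(data$counts[, cohort_rna$sample_id, drop = FALSE])
  expressed <- filter_expressed(logcpm, cohort_rna, config$link$threshold)
  gene_stats <- fit_gene_model(logcpm, cohort_rna)
  links <- link_dmrs(dmrs, gene_stats, expressed)
  link_cor <- if (nrow(links) >= 3) correlate_links(links, config$link$promoter_only) else NULL

  paths <- c(
    sample_sheet = write_table_artifact(data$cohort, file.path(out_dir, "sample_sheet.tsv"), header),
    beta = write_matrix(data$beta, file.path(out_dir, "beta.tsv"), "probe_id", header),
    qc_flags = write_table_artifact(qc$flags, file.path(out_dir, "qc_flags.tsv"), header),
    rna_qc = write_table_artifact(rna_qc, file.path(out_dir, "rna_qc.tsv"), header),
    varpart = write_table_artifact(vp$aggregated, file.path(out_dir, "varpart.tsv"), header),
    varpart_per_pc = write_table_artifact(vp$per_pc, file.path(out_dir, "varpart_per_pc.tsv"), header),
    mds = write_table_artifact(mds, file.path(out_dir, "mds.tsv"), header),
    cpg_stats = write_table_artifact(
      dplyr::select(stats, -dplyr::any_of("probe_idx")),
      file.path(out_dir, "cpg_stats.tsv"), header),
    dmrs = write_table_artifact(
      dplyr::select(tibble::as_tibble(dmrs), -dplyr::any_of("probe_idx")),
      file.path(out_dir, "dmrs.tsv"), header),
    links = write_table_artifact(links, file.path(out_dir, "links.tsv"), header))
  if (nrow(dmrs) > 0) {
    paths <- c(paths, dmr_bed = write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed")))
  }

  manifest <- tibble::tibble(
    artifact = names(paths), path = unname(paths),
    md5 = unname(tools::md5sum(unname(paths))))
  structure(list(manifest = manifest,
                 results = list(data = data, qc = qc, rna_qc = rna_qc,
                                varpart = vp, mds = mds, cpg_stats = stats,
                                lambda = lam, dmrs = dmrs, links = links,
                                link_correlation = link_cor),
                 config = config, out_dir = out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$results
  cat(sprintf("<pipeline_run> seed %d, %d artifacts in %s\n",
              x$config$seed, nrow(x$manifest), x$out_dir))
  cat(sprintf("  %d samples, %d probes; lambda = %.3f; %d DMR(s) (%d significant); %d link(s)\n",
              nrow(r$data$cohort), nrow(r$data$beta), r$lambda$lambda,
              nrow(r$dmrs), sum(r$dmrs$significant), nrow(r$links)))
  invisible(x)
}
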