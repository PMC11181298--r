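# Shared small synthetic datasets, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# small study-like dataset for structural checks
small_dataset <- function() {
  cached("small", simulate_dataset(
    sim_config(n_probes = 400, n_age_cpgs = 80, n_dmrs = 3, probes_per_dmr = 5,
               n_genes = 300, n_linked_genes = 3, seed = 101)))
}

# moderately powered cohort for model checks: 40 donors, 2 regions each
powered_dataset <- function() {
  cached("powered", simulate_dataset(
    sim_config(n_donors = 40, regions_per_donor = 2, p_mood = 0.5,
               n_probes = 600, n_age_cpgs = 100, n_dmrs = 4, probes_per_dmr = 6,
               n_genes = 400, n_linked_genes = 4, seed = 202)))
}

auto_probes <- function(d) {
  d$annotation$probe_id[d$annotation$probe_class == "autosomal"]
}

# sorted CpG stats table with arbitrary p values for DMR-caller tests
toy_stats <- function(p, pos = seq_along(p) * 100L, chrom = "chr1",
                      effect = rep(1, length(p))) {
  tibble::tibble(probe_id = sprintf("cg%04d", seq_along(p)),
                 chrom = chrom, pos = as.integer(pos),
                 effect = effect, p = p, p_adjusted = p)
}
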