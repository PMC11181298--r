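# dmrpipe

Differential-methylation analysis for EPIC-style CpG array studies in which
each donor contributes samples from several tissues or brain regions —
the setting of postmortem psychiatric methylome studies, where the strongest
signal in the data is the *individual*, and diagnosis effects are small,
regional, and entangled with age and sex.

dmrpipe is for analysts who have (or want to simulate) a beta-value matrix
with probe annotation, a detection p-value matrix, a per-sample metadata
sheet, and optionally an RNA count matrix, and who want a reproducible path
from QC to differentially methylated regions (DMRs) and their expression
consequences.

## What it computes

Working on M-values, $M = \log_2\!\big(\beta/(1-\beta)\big)$:

* **QC** — detection call rates (fraction of probes with detection
  $p < 5\times10^{-5}$; samples under 97% flagged), a two-means sex check on
  sex-chromosome methylation, donor identity verification on the array's 59
  SNP fingerprint probes, and RNA sample filters (≥10M aligned reads, ≤20%
  ribosomal, ≥10% coding).
* **Variance partitioning** — PCA of age/sex-adjusted M-values; per
  principal component, one-way ANOVA fractions $SS_{between}/SS_{total}$ per
  factor (regression $R^2$ for age), aggregated over the top 20 components
  weighted by component variance. Classical Torgerson MDS for visualization.
* **Per-CpG differential methylation** — for every probe, the
  random-intercept model
  $M \sim \text{mood} + \text{age} + \text{sex} + \text{region} + (1\,|\,\text{donor})$
  fitted by a fast profiled REML (one shared eigendecomposition of the donor
  grouping; all probes solved on a variance-ratio grid with per-probe
  refinement), plus per-region OLS models, and genomic-inflation correction
  ($\lambda_{GC}$, applied multiplicatively or as genomic control when
  $\lambda_{GC} > 1$).
* **DMR calling** — a combined-p-value scan: distance-binned autocorrelation
  of the $z$-transformed p-value track, seed-and-extend candidate regions
  (p < 0.05, gap ≤ 500 bp, ≥ 3 probes), Stouffer–Liptak combination
  $z_c = \sum_i z_i / \sqrt{\sum_{ij}\rho_{ij}}$, and Sidak correction
  $p_{sidak} = 1-(1-p_{region})^{k}$ with $k$ the covered-bases /
  region-width effective test count. BED6+ export.
* **Expression linkage** — logCPM, a mean-logCPM ≥ 1 filter in both
  diagnostic groups, the same donor random-intercept model on expression,
  and the Pearson correlation between DMR methylation differences and gene
  expression differences with its t-transform p value.
* **Synthetic cohorts** — a generator with ground truth (donor intercepts,
  age CpGs, sex separation, spatially correlated noise, contiguous DMRs,
  fingerprint genotypes, negative-binomial counts with anti-correlated
  linked genes) that powers the package's calibration and recovery tests.

## Worked example

Simulate a 40-donor, two-regions-per-donor cohort with twenty injected
mood-disorder DMRs whose promoter genes are anti-correlated with expression,
then run the full analysis:

```r
library(dmrpipe)

cfg <- sim_config(n_donors = 40, regions_per_donor = 2, p_mood = 0.5,
                  n_probes = 4000, n_age_cpgs = 500, n_dmrs = 20,
                  probes_per_dmr = 8, dmr_delta_beta = 0.15,
                  n_linked_genes = 20, seed = 1)
d <- simulate_dataset(cfg)

qc_report(d$beta, d$detp, d$annotation, d$cohort)
#> <qc_report> 80 samples, 0 flag(s)
#>   call rate: min 0.9962  median 0.9980
#>   sex mismatches: 0; fingerprint concordant: TRUE

m <- beta_to_m(d$beta)
auto <- d$annotation$probe_id[d$annotation$probe_class == "autosomal"]
variance_partition(m[auto, ], d$cohort,
                   factors = c("donor_id", "region", "mood_disorder"))
#> <variance_partition> mode=separate, K=20, adjusted for: age, sex
#> # A tibble: 3 x 2
#>   factor        percent
#>   <chr>           <dbl>
#> 1 donor_id        83.1
#> 2 region          30.1
#> 3 mood_disorder    5.20

stats <- fit_cpg_mixed(m[auto, ], d$cohort, d$annotation)
(lam <- genomic_lambda(stats$p))
#> <inflation_estimate> lambda = 1.1524 over 4000 tests
stats <- inflation_adjust(stats, lam)

dmrs <- call_dmrs(stats, d$annotation)
dplyr::select(tibble::as_tibble(head(dmrs[dmrs$significant, ], 3)),
              region_id, start, end, n_probes, p_region, p_sidak, gene)
#> # A tibble: 3 x 7
#>   region_id  start    end n_probes p_region  p_sidak gene
#>   <chr>      <int>  <int>    <int>    <dbl>    <dbl> <chr>
#> 1 dmr_001    68710  69599        8 2.28e-17 2.04e-14 G0001
#> 2 dmr_002   126296 126788        5 1.04e- 7 1.67e- 4 G0002
#> 3 dmr_003   188643 189435        7 2.67e- 9 2.68e- 6 G0003

logcpm <- log_cpm(d$counts)
links <- link_dmrs(dmrs, fit_gene_model(logcpm, d$cohort),
                   filter_expressed(logcpm, d$cohort))
correlate_links(links, promoter_only = TRUE)
#> <link_correlation> r = -0.7563 (n = 20, two-sided p = 0.0001142)
```

Reading the output: no sample fails QC; the donor grouping dominates
methylome variance (one-way donor fractions also absorb any donor-level
structure, see the methods vignette), region is modest, diagnosis small;
per-CpG tests show mild inflation, corrected before region calling; 20 of
the 20 injected DMRs reach Sidak significance, each annotated to its
promoter gene; and across the DMR–gene pairs, hypermethylation pairs with
reduced expression (r = −0.76).

The same pipeline runs end-to-end with `run_pipeline(pipeline_config(...))`,
which writes every table as TSV plus a BED file and an md5 manifest, and is
byte-reproducible for a fixed seed. A thin command-line wrapper with
`simulate | qc | varpart | dmtest | dmr | link | all` subcommands lives at
`inst/cli/dmrpipe.R`.

Plotting helpers: `autoplot()` on variance partitions and MDS results,
`plot_qq()` for p-value inflation, `plot_links()` for methylation–expression
scatter; `tidy()`/`glance()` methods cover the fitted result objects.

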