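---
title: "Models and methods in dmrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dmrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrpipe)
```

dmrpipe analyzes CpG methylation from Illumina EPIC-style arrays in cohorts
where each donor contributes samples from several brain regions, and asks two
questions: which factors (individual, age, sex, region, diagnosis) drive
methylome variability, and where along the genome does methylation differ
between donors with a mood disorder and controls — and does that difference
track gene expression. This vignette explains the models, the defaults, the
synthetic-data generator used for validation, and the choices made where the
design was open.

## Measurement scale

Arrays report per-CpG beta values (methylated signal fraction, in $[0,1]$).
All modeling happens on the M-value scale,

$$M = \log_2\frac{\beta}{1-\beta},$$

which stabilizes variance near the boundaries. `beta_to_m()` clips beta into
$[\varepsilon, 1-\varepsilon]$ first (default $\varepsilon = 10^{-6}$,
configurable in $(0, 0.01]$) so boundary values stay finite; the base-2 logit
is the array literature's M-value convention.

## Quality control

* **Detection call rate** (`detection_call_rate()`): the fraction of a
  sample's probes with detection $p$ strictly below $5\times10^{-5}$; samples
  below a 0.97 call rate are flagged. Both thresholds follow the common EPIC
  QC practice of requiring >97% of probes detected at
  $p < 5\times 10^{-5}$; the inequality is strict, so a probe exactly at the
  threshold counts as undetected.
* **Sex check** (`infer_sex()`): samples are summarized by their mean
  sex-chromosome M-value and split by deterministic 1-D two-means
  (centers initialized at the extremes). Each cluster takes the majority
  reported sex of its members; disagreements are flagged. This is the
  smallest method that can verify the reported labels; if the two clusters
  coincide the result is declared indeterminate rather than guessed.
* **SNP fingerprints** (`fingerprint_concordance()`): the EPIC array carries
  59 genotype-reporting probes. Pairwise sample distance is the mean absolute
  beta difference over those probes; single-linkage clustering at 0.1 should
  reproduce the donor grouping, because genotype is constant within a donor.
  Both a donor split across clusters and a cluster spanning donors are
  flagged.
* **RNA sample QC** (`rna_sample_qc()`): fail if aligned reads < 10 million,
  or ribosomal fraction > 20%, or coding fraction < 10% (all strict). The
  pipeline consumes a precomputed alignment-metrics table; read alignment
  itself is out of scope.

## Variance partitioning

`variance_partition()` follows a PCA + per-component ANOVA recipe:

1. Optionally residualize each probe on age (numeric) and sex (binary) by
   ordinary least squares (`residualize()`).
2. PCA across samples with per-probe centering and no scaling (M-values share
   a scale), keeping the top $K = 20$ components by default.
3. For every component, the variance fraction attributable to a factor: the
   one-way ANOVA ratio $SS_{between}/SS_{total}$ for categorical factors, the
   simple-regression $R^2$ for numeric ones.
4. Aggregate over components weighted by component variance:
   $100\cdot\sum_k f_k v_k / \sum_k v_k$.

Two ANOVA modes exist because the design is genuinely open. In `"separate"`
mode (default) each factor is fitted alone; overlapping factors — donor
subsumes sex, diagnosis, and any other donor-level variable — are reported
side by side, and percentages need not sum to 100. In `"sequential"` mode a
joint linear model is fitted per component in the order given and sequential
sums of squares (plus residual) sum to exactly 1. A joint model containing
donor *and* diagnosis is not estimable (donor is collinear with every
donor-level factor), which is why "separate" is the default for
donor-containing factor lists.

Two consequences of the one-way estimator deserve emphasis. First, under a
pure-noise null its expectation is not zero but $(g-1)/(n-1)$ for $g$ groups
and $n$ samples — with many donors and few samples per donor the donor
fraction carries substantial upward bias. Second, the donor grouping absorbs
every donor-constant variable, so donor percentages reported *without* age
and sex adjustment include the age and sex contributions. Both effects are
inherent to the method, not bugs; the recovery test below is designed so that
they are negligible.

`classical_mds()` provides the visual counterpart: Torgerson double-centering
MDS on Euclidean distances over the most variable probes (default 1000), with
a metadata flag when fewer positive eigenvalues than requested dimensions
exist.

## Per-CpG differential methylation

The cross-region model per probe is a random-intercept model

$$M_{ij} = \beta_0 + \beta_1\,\text{mood}_i + \beta_2\,\text{age}_i +
\beta_3\,\text{sex}_i + \boldsymbol\gamma\,\text{region}_{ij} + b_i +
\varepsilon_{ij},\qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij}\sim
N(0,\sigma^2),$$

fitted by REML, with the mood coefficient (M difference, mood − control)
reported with its $t$ statistic. Because the design matrix and donor grouping
are identical across probes, `fit_cpg_mixed()` profiles the REML criterion in
the single variance ratio $\lambda = \sigma_b^2/\sigma^2$: the donor
relatedness matrix is eigendecomposed once, the criterion is evaluated for
all probes on a $\lambda$ grid (0 plus 91 log-spaced points in
$[10^{-3}, 10^{3}]$) via per-group sufficient statistics, and each probe's
optimum is refined by parabolic interpolation in $\log\lambda$. This is exact
in the same sense as a generic mixed-model optimizer up to the grid
refinement; the test suite checks agreement with `lme4::lmer` to ~$10^{-3}$
on effects. No empirical-Bayes moderation or precision weighting is applied:
the model is a plain per-probe random-intercept fit, which keeps every probe
statistically self-contained and deterministic.

Degrees of freedom use the residual approximation
$\nu = n - p - q + 1$ ($q$ donors, $p$ fixed effects). For a between-donor
contrast this is close to the natural donor-level df
($q$ − donor-level parameters); Satterthwaite-style approximations are
deliberately out of scope for determinism and simplicity. Probes with a
degenerate fit (zero residual variance) keep their coefficient but report
`NA` statistics and are counted in the `n_failed` attribute.

Per region, `fit_cpg_fixed()` is ordinary least squares
$M \sim \text{mood} + \text{age} + \text{sex}$ with $n-4$ df, requiring one
sample per donor and $n > 4$.

**Genomic inflation.** `genomic_lambda()` reports
$\lambda_{GC} = \mathrm{median}(\chi^2_{obs}) / 0.4549$, the usual
genomic-control factor on the implied 1-df chi-squares.
`inflation_adjust()` offers two corrections, applied only when
$\lambda_{GC} > 1$ (deflation is never "corrected", which would shrink p
values): the literal rule $p_{adj} = \min(1, p\cdot\lambda_{GC})$ (default),
and the standard genomic-control division of the chi-square statistic by
$\lambda_{GC}$. The multiplicative rule preserves p-value ranking exactly;
the division rule is provided because it is the standard form. The adjusted
p values feed the DMR caller.

## DMR calling

`call_dmrs()` reimplements the combined-p-value (comb-p-style) scan:

1. **ACF estimation** (`estimate_acf()`): for distance bins (default 100 bp
   up to 1000 bp), the Pearson correlation of $z = \Phi^{-1}(1-p)$ over probe
   pairs at that distance. Bins with fewer than 50 pairs inherit the previous
   bin; negative estimates are floored at 0 before matrix construction so
   region correlation matrices stay positive semidefinite (a nearest-PSD
   eigenvalue repair is a flagged safety net).
2. **Candidate scan** (`find_candidate_regions()`): probes with
   $p < 0.05$ are chained left-to-right whenever consecutive sub-threshold
   probes lie within 500 bp; chains with ≥ 3 probes survive. The scan
   parameters are defaults, exposed in config — the region concept, not a
   particular parameterization, is what is being reproduced.
3. **Stouffer–Liptak scoring** (`stouffer_liptak()`):
   $z_c = \sum_i z_i / \sqrt{\sum_{ij}\rho_{ij}}$ with $\rho$ looked up from
   the binned ACF by pair distance (0 beyond the last bin); $p_{region}$ is
   the upper normal tail. With identity correlation this is the classical
   Stouffer combination; with an all-ones matrix it returns the shared p
   unchanged. P values are clipped to $[10^{-300}, 1-10^{-16}]$ before the
   z transform.
4. **Sidak correction** (`sidak_correct()`): the effective number of tests
   for a region of width $w$ is $k = \max(1,\ C/w)$, where the covered bases
   $C$ are approximated by (number of tested probes) × (median inter-probe
   spacing); $p_{sidak} = 1-(1-p_{region})^k$, computed via
   `expm1`/`log1p` so small p values survive. Exact covered-base bookkeeping
   would require the caller's index structures for little practical change.
5. **Annotation** (`annotate_dmrs()`): majority gene symbol among member
   probes (ties broken lexicographically and flagged); promoter if any
   member probe is a promoter probe. Gene and promoter flags are inputs in
   the probe annotation — no annotation source is bundled, because which
   annotation defines a "promoter" is a user decision.

## Expression linkage

`log_cpm()` uses the `log2((count + 0.5)/(libsize + 1) * 1e6)` offset
convention; the exact offsets are a documented choice, fixed for
determinism. `filter_expressed()` keeps genes with mean logCPM ≥ 1
(inclusive) in *both* diagnostic groups. `fit_gene_model()` applies exactly
the same donor random-intercept machinery to logCPM rows — the
differential-expression model is run parallel to the methylation model, with
no precision weighting for the same reason as above. `link_dmrs()` pairs
each gene-annotated DMR passing the filter with its gene's log2 fold change,
flagging pointwise $p < 0.05$ (deliberately uncorrected — the linkage is
exploratory). `correlate_links()` computes the Pearson correlation between
the DMR methylation difference and the expression difference across links,
with the two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. The
correlation is computed on group-difference pairs (one point per DMR–gene
pair), not per-sample values: the linkage question is whether *differences*
co-vary. A per-sample mode would be a different statistic and is not
implemented.

## The synthetic-data generator

`simulate_dataset()` generates cohorts with the statistical structure the
analysis assumes, plus ground truth for recovery tests. Defaults describe
the study-like conditions: 22 donors contributing 56 samples across four
brain regions (twelve donors with three regions, ten with two), ages uniform
on [21, 103] years, sex Bernoulli(0.5), 13/22 of donors with a mood
disorder (split MDD:bipolar 10:3; non-mood donors control:schizophrenia
8:1), postmortem delay ~N(454, 116) minutes.

Methylation is built on the M scale and mapped to beta by the inverse logit,
so the downstream logit transform is exact:

* per-probe bimodal baseline (low/high methylation mixture);
* donor random intercepts, per probe, $N(0, 0.9^2)$ — the dominant component;
* linear age slopes on a probe subset, slope $N(0, 0.06^2)$ per year (with a
  uniform [21,103] age distribution this puts age around 20% of M variance);
* per-(probe, region) offsets $N(0, 0.5^2)$;
* mood-disorder DMRs: runs of 8 consecutive probes whose baseline beta is
  drawn in [0.2, 0.45] so that the configured +Δβ (default 0.15) stays
  interior to (0,1); the M-scale shift is the logit-equivalent of Δβ at the
  probe's baseline. Per-DMR magnitudes are scaled by a Uniform(0.5, 1.5)
  multiplier so regions differ in strength (set `dmr_effect_range = c(1, 1)`
  for homogeneous effects);
* spatially correlated residual noise, sd 0.7, with correlation
  $e^{-d/400\text{bp}}$ realized as a Markov process along the chromosome;
* probe spacing exponential with mean 300 bp, except inside DMR runs where
  the mean is 100 bp — array DMRs sit in CpG-island-like dense stretches,
  and a "true region" whose internal gaps exceed any reasonable scan gap
  would not be a region in any caller's sense;
* sex-chromosome probes: females intermediate (X-inactivation-like), males
  hypomethylated, so per-sample means separate the sexes;
* the 59 fingerprint probes take beta in {0.05, 0.5, 0.95} constant within
  donor with small beta-scale technical noise (zero when `noise_sd = 0`).

With these defaults the realized variance decomposition is roughly donor
40%, age 20%, region 10%, residual 25–30%, mirroring the regime the method
is meant for (individual effects largest; region and diagnosis minor).
Expression is negative binomial (dispersion 0.1) with a bimodal baseline
(~30% lowly expressed genes, so the logCPM filter has a real population to
remove); genes linked to promoter DMRs receive a mood log2 fold change of
magnitude 1 × (the DMR's effect multiplier) with sign opposite to the
methylation change. Ground truth records DMR intervals, age-CpG ids, the
linked-gene map, and the realized per-factor variance fractions computed
from the generator's own component matrices.

What the generator does **not** emulate: probe type I/II design bias, dye
bias, normalization artifacts, cell-composition heterogeneity, batch
effects, and genuine genome-wide annotation. Passing tests therefore
demonstrate statistical correctness of the pipeline under its assumed model,
not robustness to array technical artifacts.

## Validation design and problem sizes

The test suite checks, among others (sizes chosen to keep a full run within
a few minutes):

* type-I calibration of the mixed model on null cohorts (40 donors × 2
  regions, 5,000 probes): p < 0.05 fraction in [0.04, 0.06], genomic lambda
  in [0.95, 1.05], and across 20 replicates at most one Sidak-significant
  DMR in ≥ 18;
* DMR recovery at Δβ = 0.15, 8 probes per region, 40 donors: sensitivity
  ≥ 0.8 with all significant regions overlapping truth;
* variance-partition recovery at 2,000 probes with 12 donors × 4 regions and
  low noise (sd 0.2), where the structured signal has rank below K = 20 and
  the one-way ANOVA null bias is negligible, after age/sex adjustment
  (truth renormalized over the surviving components): within ±5 percentage
  points;
* Stouffer–Liptak against 100,000-draw correlated-normal Monte Carlo on 50
  random regions;
* the closed-form promoter-linkage example: r = −0.5531 over n = 12 pairs
  gives two-sided p = 0.0622;
* byte-identical pipeline re-runs under a fixed seed.

## Known limitations

* The residual-df approximation can be mildly anticonservative for heavily
  unbalanced donor structures; the calibration tests bound this at the
  study-like sizes only.
* The one-way ANOVA variance fractions are biased upward for factors with
  many levels (donor); interpret them as the method's output, comparable
  across datasets analyzed the same way, not as unbiased variance-component
  estimates.
* The Sidak effective-test count approximates covered bases by probe count ×
  median spacing; trackwide irregular spacing shifts k modestly.
* Correction by multiplying p values with lambda (the default, kept for
  fidelity) is nonstandard; the genomic-control mode is the statistically
  conventional alternative.
* Methylation–expression linkage is exploratory: pointwise significance,
  no multiplicity correction, group-difference correlation over a small
  number of pairs.
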