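# Synthetic cohort / methylation / expression generator with ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# donor random intercepts as the dominant variance component, linear age
# effects on a subset of CpGs, sex-chromosome separation by sex, small
# region offsets, contiguous mood-disorder DMRs, spatially autocorrelated
# residuals along the chromosome, SNP-fingerprint probes constant within
# donor, and negative-binomial RNA counts with promoter-DMR-linked genes
# anti-correlated with methylation.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic cohort generator.
#' Defaults describe a study-like cohort: 22 donors contributing 56 samples
#' across up to four brain regions, ages uniform on \[21, 103\] years, about
#' 59% of donors with a mood disorder, and variance components on the M-value
#' scale sized so that donor explains the largest share of methylation
#' variance (~40%), age ~20%, and region ~10%.
#'
#' @param n_donors Number of donors.
#' @param regions_per_donor Samples per donor, each from a distinct region
#'   (1-4). Scalar or length-`n_donors` integer vector; the default vector
#'   yields 56 samples from 22 donors.
#' @param p_mood Probability that a donor carries a mood-disorder diagnosis
#'   (MDD or bipolar).
#' @param n_probes Number of autosomal CpG probes (a single chromosome).
#' @param n_age_cpgs Number of probes given a linear age slope.
#' @param n_dmrs Number of injected mood-disorder DMRs.
#' @param probes_per_dmr Consecutive probes per DMR (>= 3).
#' @param dmr_delta_beta Target beta-scale methylation increase in mood
#'   samples at DMR probes, in (0, 0.5).
#' @param dmr_effect_range Length-2 range of the per-DMR effect multiplier,
#'   drawn Uniform(`dmr_effect_range[1]`, `dmr_effect_range[2]`); the default
#'   c(0.5, 1.5) makes regions differ in strength (set to c(1, 1) for a
#'   homogeneous effect).
#' @param donor_sd,age_slope_sd,region_sd,noise_sd Standard deviations of the
#'   M-scale variance components: donor random intercept, per-year age slope,
#'   per-(probe, region) offset, and residual noise.
#' @param acf_decay Base-pair scale of the exponential spatial correlation of
#'   residuals, `cor = exp(-d / acf_decay)`.
#' @param probe_spacing_mean Mean inter-probe spacing in base pairs.
#' @param dmr_spacing_mean Mean spacing within injected DMR probe runs
#'   (CpG-island-like density), base pairs.
#' @param n_sex_probes,n_fingerprint_probes Numbers of sex-chromosome and
#'   SNP-fingerprint probes (the EPIC array carries 59 fingerprint probes).
#' @param detp_fail_rate Per-(probe, sample) probability of a failed detection
#'   p value.
#' @param n_genes Number of genes in the RNA count matrix.
#' @param n_linked_genes Number of genes linked to DMR promoters
#'   (<= `n_dmrs`).
#' @param linked_logfc Base log2 fold-change magnitude for linked genes
#'   (scaled by the matching DMR's effect multiplier, sign opposite to the
#'   methylation change).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param libsize_range Length-2 numeric, range of per-sample library sizes.
#' @param rna_qc_fail_rate Fraction of samples given failing RNA QC metrics.
#' @param seed Integer seed; every generator call is deterministic given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 22,
                       regions_per_donor = c(rep(3L, 12), rep(2L, 10)),
                       p_mood = 13 / 22,
                       n_probes = 3000,
                       n_age_cpgs = 600,
                       n_dmrs = 10,
                       probes_per_dmr = 8,
                       dmr_delta_beta = 0.15,
                       dmr_effect_range = c(0.5, 1.5),
                       donor_sd = 0.9,
                       age_slope_sd = 0.06,
                       region_sd = 0.5,
                       noise_sd = 0.7,
                       acf_decay = 400,
                       probe_spacing_mean = 300,
                       dmr_spacing_mean = 100,
                       n_sex_probes = 100,
                       n_fingerprint_probes = 59,
                       detp_fail_rate = 0.002,
                       n_genes = 2000,
                       n_linked_genes = min(n_dmrs, 10),
                       linked_logfc = 1,
                       nb_dispersion = 0.1,
                       libsize_range = c(1e6, 5e6),
                       rna_qc_fail_rate = 0,
                       seed = 1L) {
  config <- list(
    n_donors = n_donors, regions_per_donor = regions_per_donor,
    p_mood = p_mood, n_probes = n_probes, n_age_cpgs = n_age_cpgs,
    n_dmrs = n_dmrs, probes_per_dmr = probes_per_dmr,
    dmr_delta_beta = dmr_delta_beta, dmr_effect_range = dmr_effect_range,
    donor_sd = donor_sd,
    age_slope_sd = age_slope_sd, region_sd = region_sd, noise_sd = noise_sd,
    acf_decay = acf_decay, probe_spacing_mean = probe_spacing_mean,
    dmr_spacing_mean = dmr_spacing_mean,
    n_sex_probes = n_sex_probes, n_fingerprint_probes = n_fingerprint_probes,
    detp_fail_rate = detp_fail_rate, n_genes = n_genes,
    n_linked_genes = n_linked_genes, linked_logfc = linked_logfc,
    nb_dispersion = nb_dispersion, libsize_range = libsize_range,
    rna_qc_fail_rate = rna_qc_fail_rate, seed = as.integer(seed))
  validate_sim_config(config)
}

#' @rdname sim_config
#' @param config A list of the fields above.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  counts <- c("n_donors", "n_probes", "probes_per_dmr", "n_genes")
  for (f in counts) {
    if (length(config[[f]]) != 1 || config[[f]] < 1) {
      abort_dmrpipe(sprintf("%s must be a positive count", f), "dmrpipe_config_error")
    }
  }
  for (f in c("n_dmrs", "n_age_cpgs", "n_linked_genes")) {
    if (length(config[[f]]) != 1 || config[[f]] < 0) {
      abort_dmrpipe(sprintf("%s must be a nonnegative count", f), "dmrpipe_config_error")
    }
  }
  rpd <- config$regions_per_donor
  if (!length(rpd) %in% c(1L, config$n_donors)) {
    abort_dmrpipe("regions_per_donor must be scalar or one value per donor",
                  "dmrpipe_config_error")
  }
  if (any(rpd < 1) || any(rpd > 4)) {
    abort_dmrpipe("regions_per_donor must be between 1 and 4 (four regions exist)",
                  "dmrpipe_config_error")
  }
  if (config$n_dmrs > 0 &&
      (config$dmr_delta_beta <= 0 || config$dmr_delta_beta >= 0.5)) {
    abort_dmrpipe("dmr_delta_beta must lie in (0, 0.5)", "dmrpipe_config_error")
  }
  if (config$probes_per_dmr * config$n_dmrs > config$n_probes) {
    abort_dmrpipe("probes_per_dmr * n_dmrs must not exceed n_probes",
                  "dmrpipe_config_error")
  }
  if (config$n_linked_genes > config$n_dmrs) {
    abort_dmrpipe("n_linked_genes must not exceed n_dmrs", "dmrpipe_config_error")
  }
  if (config$n_dmrs > 0 && config$probes_per_dmr < 3) {
    abort_dmrpipe("probes_per_dmr must be at least 3", "dmrpipe_config_error")
  }
  der <- config$dmr_effect_range
  if (length(der) != 2 || der[1] <= 0 || der[1] > der[2]) {
    abort_dmrpipe("dmr_effect_range must be 0 < lo <= hi", "dmrpipe_config_error")
  }
  if (config$p_mood < 0 || config$p_mood > 1) {
    abort_dmrpipe("p_mood must be a proportion", "dmrpipe_config_error")
  }
  if (config$nb_dispersion < 0) {
    abort_dmrpipe("nb_dispersion must be nonnegative", "dmrpipe_config_error")
  }
  structure(config, class = "sim_config")
}

#' Simulate a cohort of donors and samples
#'
#' Donor ages are uniform on \[21, 103\] years, sex is Bernoulli(0.5), and a
#' donor is assigned a mood-disorder diagnosis with probability `p_mood`
#' (split MDD:bipolar 10:3 as in the emulated study; non-mood donors are
#' control or schizophrenia 8:1). Each donor contributes one sample from each
#' of `regions_per_donor` distinct brain regions.
#'
#' @param config A [sim_config()].
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(unclass(config))
  withr::with_seed(config$seed, {
    n <- config$n_donors
    donors <- sprintf("D%03d", seq_len(n))
    age <- runif(n, 21, 103)
    sex <- ifelse(runif(n) < 0.5, "female", "male")
    mood <- runif(n) < config$p_mood
    diagnosis <- ifelse(
      mood,
      ifelse(runif(n) < 10 / 13, "MDD", "bipolar"),
      ifelse(runif(n) < 8 / 9, "control", "schizophrenia"))
    rpd <- rep_len(config$regions_per_donor, n)
    cohort <- purrr::map_dfr(seq_len(n), function(i) {
      regions <- sample(REGION_LEVELS, rpd[i])
      tibble::tibble(
        sample_id = paste(donors[i], regions, sep = "_"),
        donor_id = donors[i],
        age = age[i],
        sex = sex[i],
        diagnosis = diagnosis[i],
        region = regions,
        postmortem_delay = pmax(60, rnorm(rpd[i], 454, 116)))
    })
    validate_cohort(cohort)
  })
}

# Non-overlapping runs of probes_per_dmr consecutive probe indices, evenly
# spread along the chromosome.
place_dmrs <- function(n_probes, n_dmrs, probes_per_dmr) {
  if (n_dmrs == 0) return(list())
  anchors <- floor(seq_len(n_dmrs) * n_probes / (n_dmrs + 1))
  purrr::map(anchors, function(a) seq.int(a, length.out = probes_per_dmr))
}

#' Simulate methylation data for a cohort
#'
#' Generates probe annotation, a beta-value matrix, detection p values, and
#' ground truth. Effects are built on the M-value scale and mapped to beta by
#' the inverse logit, so the downstream logit transform recovers them exactly:
#' per-probe bimodal baseline + donor intercept + age slope (age CpGs) +
#' region offset + DMR effect (mood samples only) + spatially correlated
#' noise (exponential kernel along the chromosome, realised as a Markov
#' process). Sex-chromosome probes get sex-dependent means; fingerprint
#' probes take beta in {0.05, 0.5, 0.95} constant within donor.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param config A [sim_config()].
#' @return A list with elements `beta` (matrix), `detp` (matrix),
#'   `annotation` (tibble), and `truth` (list: `true_dmr_intervals`,
#'   `age_cpg_ids`, `dmr_effect_multiplier`, `linked_gene_map`,
#'   `true_variance_fractions`).
#' @export
simulate_methylation <- function(cohort, config) {
  config <- validate_sim_config(unclass(config))
  cohort <- validate_cohort(cohort)
  withr::with_seed(config$seed + 1L, {
    n_smp <- nrow(cohort)
    np <- config$n_probes

    spacing <- pmax(10, round(stats::rexp(np, 1 / config$probe_spacing_mean)))
    dmr_idx <- place_dmrs(np, config$n_dmrs, config$probes_per_dmr)
    # DMRs live in CpG-island-like dense stretches: tighter spacing inside runs
    within <- unlist(lapply(dmr_idx, function(ii) ii[-1]))
    spacing[within] <- pmax(10, round(stats::rexp(length(within),
                                                  1 / config$dmr_spacing_mean)))
    pos <- cumsum(spacing) + 10000L
    auto <- tibble::tibble(
      probe_id = sprintf("cg%06d", seq_len(np)),
      chrom = "chr1", pos = as.integer(pos),
      probe_class = "autosomal", gene = NA_character_, promoter = FALSE)

    dmr_gene <- sprintf("G%04d", seq_len(config$n_dmrs))
    for (d in seq_along(dmr_idx)) {
      auto$gene[dmr_idx[[d]]] <- dmr_gene[d]
      auto$promoter[dmr_idx[[d]]] <- TRUE
    }

    # bimodal baseline; DMR probes start in [0.2, 0.45] beta so the positive
    # shift stays interior to (0, 1)
    low <- runif(np) < 0.5
    base_m <- ifelse(low, rnorm(np, -2.5, 0.8), rnorm(np, 2.5, 0.8))
    in_dmr <- unlist(dmr_idx)
    base_m[in_dmr] <- logit2(runif(length(in_dmr), 0.2, 0.45))

    age_pool <- setdiff(seq_len(np), in_dmr)
    n_age <- min(config$n_age_cpgs, length(age_pool))
    age_idx <- sort(sample(age_pool, n_age))
    slopes <- numeric(np)
    slopes[age_idx] <- rnorm(n_age, 0, config$age_slope_sd)

    donors <- unique(cohort$donor_id)
    donor_fx <- matrix(rnorm(np * length(donors), 0, config$donor_sd),
                       np, dimnames = list(NULL, donors))
    region_fx <- matrix(rnorm(np * 4, 0, config$region_sd),
                        np, dimnames = list(NULL, REGION_LEVELS))

    u_mult <- runif(config$n_dmrs, config$dmr_effect_range[1],
                    config$dmr_effect_range[2])
    dmr_delta_m <- numeric(np)
    for (d in seq_along(dmr_idx)) {
      ii <- dmr_idx[[d]]
      b0 <- inv_logit2(base_m[ii])
      b1 <- pmin(1 - 1e-3, b0 + u_mult[d] * config$dmr_delta_beta)
      dmr_delta_m[ii] <- logit2(b1) - base_m[ii]
    }

    age_c <- cohort$age - mean(cohort$age)
    comp_donor <- donor_fx[, cohort$donor_id, drop = FALSE]
    comp_age <- outer(slopes, age_c)
    comp_region <- region_fx[, cohort$region, drop = FALSE]
    comp_dmr <- outer(dmr_delta_m, as.numeric(cohort$mood_disorder))

    # exponential spatial correlation = nonstationary AR(1) along position
    rho <- exp(-spacing[-1] / config$acf_decay)
    noise <- matrix(0, np, n_smp)
    noise[1, ] <- rnorm(n_smp)
    innov <- matrix(rnorm((np - 1) * n_smp), np - 1, n_smp)
    scale <- sqrt(1 - rho^2)
    for (i in 2:np) {
      noise[i, ] <- rho[i - 1] * noise[i - 1, ] + scale[i - 1] * innov[i - 1, ]
    }
    comp_noise <- config$noise_sd * noise

    m_auto <- base_m + comp_donor + comp_age + comp_region + comp_dmr + comp_noise

    # sex-chromosome probes: females intermediate (X inactivation), males
    # hypomethylated -> per-sample mean M separates the sexes
    ns <- config$n_sex_probes
    sex_ann <- tibble::tibble(
      probe_id = sprintf("cgX%05d", seq_len(ns)),
      chrom = "chrX",
      pos = as.integer(seq_len(ns) * 1000L),
      probe_class = "sex_chromosome", gene = NA_character_, promoter = FALSE)
    m_female <- rnorm(ns, 0, 0.4)
    m_male <- rnorm(ns, -3, 0.4)
    m_sex <- matrix(0, ns, n_smp)
    is_f <- cohort$sex == "female"
    m_sex[, is_f] <- m_female
    m_sex[, !is_f] <- m_male
    m_sex <- m_sex + config$noise_sd * matrix(rnorm(ns * n_smp), ns, n_smp)

    # fingerprint probes: genotype-like beta constant within donor
    nf <- config$n_fingerprint_probes
    fp_ann <- tibble::tibble(
      probe_id = sprintf("rs%05d", seq_len(nf)),
      chrom = "chr0",
      pos = as.integer(seq_len(nf) * 1000L),
      probe_class = "snp_fingerprint", gene = NA_character_, promoter = FALSE)
    geno <- matrix(sample(c(0.05, 0.5, 0.95), nf * length(donors),
                          replace = TRUE, prob = c(0.25, 0.5, 0.25)),
                   nf, dimnames = list(NULL, donors))
    # genotype probes form tight beta clusters: small technical noise on the
    # beta scale (zero when noise_sd is zero)
    fp_beta <- geno[, cohort$donor_id, drop = FALSE] +
      0.03 * (config$noise_sd > 0) * matrix(rnorm(nf * n_smp), nf, n_smp)
    m_fp <- logit2(pmin(pmax(fp_beta, 0.001), 0.999))

    annotation <- dplyr::bind_rows(auto, sex_ann, fp_ann)
    m_all <- rbind(m_auto, m_sex, m_fp)
    rownames(m_all) <- c(auto$probe_id, sex_ann$probe_id, fp_ann$probe_id)
    colnames(m_all) <- cohort$sample_id
    beta <- inv_logit2(m_all)

    detp <- matrix(runif(length(m_all), 0, 1e-6), nrow(m_all), ncol(m_all),
                   dimnames = dimnames(m_all))
    fails <- runif(length(detp)) < config$detp_fail_rate
    detp[fails] <- runif(sum(fails), 0.1, 1)

    intervals <- purrr::map_dfr(seq_along(dmr_idx), function(d) {
      ii <- dmr_idx[[d]]
      tibble::tibble(
        dmr = d, chrom = "chr1",
        start = min(auto$pos[ii]), end = max(auto$pos[ii]),
        gene = dmr_gene[d],
        mean_delta_m = mean(dmr_delta_m[ii]),
        probe_ids = list(auto$probe_id[ii]))
    })

    ss <- function(x) sum((x - mean(x))^2)
    comp_ss <- c(
      donor = sum(apply(comp_donor, 1, ss)),
      age = sum(apply(comp_age, 1, ss)),
      region = sum(apply(comp_region, 1, ss)),
      diagnosis = sum(apply(comp_dmr, 1, ss)),
      residual = sum(apply(comp_noise, 1, ss)))
    truth <- list(
      true_dmr_intervals = intervals,
      age_cpg_ids = auto$probe_id[age_idx],
      dmr_effect_multiplier = u_mult,
      linked_gene_map = tibble::tibble(
        gene = dmr_gene[seq_len(config$n_linked_genes)],
        dmr = seq_len(config$n_linked_genes)),
      true_variance_fractions = comp_ss / sum(comp_ss))

    list(beta = beta,
         detp = detp,
         annotation = validate_probe_annotation(annotation),
         truth = truth)
  })
}

#' Simulate RNA counts and alignment QC metrics
#'
#' Gene counts are negative binomial with per-sample library sizes uniform on
#' `libsize_range`. Genes named in `truth$linked_gene_map` receive a
#' mood-disorder log2 fold-change of magnitude `linked_logfc` scaled by the
#' matching DMR's effect multiplier, with sign opposite to the (positive)
#' methylation change.
#'
#' @inheritParams simulate_methylation
#' @param truth Ground-truth list from [simulate_methylation()].
#' @return A list with `counts` (integer matrix genes x samples) and
#'   `rna_qc` (tibble: sample_id, aligned_reads, ribosomal_fraction,
#'   coding_fraction).
#' @export
simulate_expression <- function(cohort, config, truth) {
  config <- validate_sim_config(unclass(config))
  cohort <- validate_cohort(cohort)
  withr::with_seed(config$seed + 2L, {
    ng <- config$n_genes
    n_smp <- nrow(cohort)
    genes <- sprintf("G%04d", seq_len(ng))

    # bimodal baseline abundance: ~30% of genes are lowly expressed so the
    # undetected-gene (mean logCPM) filter has a real population to remove
    lowly <- runif(ng) < 0.3
    base <- ifelse(lowly, rnorm(ng, -8, 2), rnorm(ng, 0, 1.5))
    lfc <- numeric(ng)
    if (nrow(truth$linked_gene_map) > 0) {
      li <- match(truth$linked_gene_map$gene, genes)
      if (anyNA(li)) {
        abort_dmrpipe("linked genes missing from the gene universe",
                      "dmrpipe_config_error")
      }
      base[li] <- rnorm(length(li), 3, 0.5)  # keep linked genes expressed
      mult <- truth$dmr_effect_multiplier[truth$linked_gene_map$dmr]
      lfc[li] <- -config$linked_logfc * mult
    }

    libsize <- runif(n_smp, config$libsize_range[1], config$libsize_range[2])
    log_mu <- outer(base, rep(1, n_smp)) +
      outer(lfc, as.numeric(cohort$mood_disorder))
    prop <- 2^log_mu
    prop <- sweep(prop, 2, colSums(prop), "/")
    mu <- sweep(prop, 2, libsize, "*")
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else 1e8
    counts <- matrix(rnbinom(ng * n_smp, mu = mu, size = size), ng,
                     dimnames = list(genes, cohort$sample_id))

    rna_qc <- tibble::tibble(
      sample_id = cohort$sample_id,
      aligned_reads = round(runif(n_smp, 1.5e7, 5e7)),
      ribosomal_fraction = runif(n_smp, 0.01, 0.10),
      coding_fraction = runif(n_smp, 0.30, 0.60))
    n_fail <- round(config$rna_qc_fail_rate * n_smp)
    if (n_fail > 0) {
      bad <- sample(n_smp, n_fail)
      mode <- sample(3, n_fail, replace = TRUE)
      rna_qc$aligned_reads[bad[mode == 1]] <- round(runif(sum(mode == 1), 1e6, 9.9e6))
      rna_qc$ribosomal_fraction[bad[mode == 2]] <- runif(sum(mode == 2), 0.25, 0.6)
      rna_qc$coding_fraction[bad[mode == 3]] <- runif(sum(mode == 3), 0.01, 0.09)
    }

    list(counts = counts, rna_qc = rna_qc)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_cohort()], [simulate_methylation()]
#' and [simulate_expression()] under one config.
#'
#' @param config A [sim_config()].
#' @return A list: `cohort`, `beta`, `detp`, `annotation`, `truth`, `counts`,
#'   `rna_qc`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  meth <- simulate_methylation(cohort, config)
  expr <- simulate_expression(cohort, config, meth$truth)
  c(list(cohort = cohort, config = config), meth, expr)
}
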