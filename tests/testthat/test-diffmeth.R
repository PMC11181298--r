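null_cohort <- function(n_donors = 20, seed = 31) {
  cfg <- sim_config(n_donors = n_donors, regions_per_donor = 2, p_mood = 0.5,
                    n_probes = 60, n_age_cpgs = 0, n_dmrs = 0, seed = seed)
  simulate_cohort(cfg)
}

test_that("the profiled-REML fitter matches lme4 on individual probes", {
  skip_if_not_installed("lme4")
  d <- powered_dataset()
  m <- beta_to_m(d$beta)[auto_probes(d), ]
  stats <- fit_cpg_mixed(m, d$cohort, d$annotation)
  expect_equal(attr(stats, "n_failed"), 0)

  co <- d$cohort
  co$sexn <- as.numeric(co$sex == "male")
  for (pid in stats$probe_id[seq(1, nrow(stats), length.out = 6)]) {
    df <- data.frame(y = m[pid, co$sample_id], mood = co$mood_disorder,
                     age = co$age, sex = co$sexn, region = co$region,
                     donor = co$donor_id)
    fit <- lme4::lmer(y ~ mood + age + sex + region + (1 | donor), df, REML = TRUE)
    row <- stats[stats$probe_id == pid, ]
    expect_equal(row$effect, unname(lme4::fixef(fit)["moodTRUE"]), tolerance = 1e-3)
    expect_equal(row$se, sqrt(as.matrix(vcov(fit))["moodTRUE", "moodTRUE"]),
                 tolerance = 1e-2)
  }
})

test_that("with no between-donor variance the mixed model collapses to OLS", {
  co <- null_cohort()
  n <- nrow(co)
  probes <- sprintf("p%02d", 1:20)
  # residuals centered within donor: between-donor variance is exactly zero,
  # so REML puts the variance ratio on the zero boundary
  m <- withr::with_seed(8, {
    e <- matrix(rnorm(20 * n), 20, n)
    for (donor in unique(co$donor_id)) {
      idx <- which(co$donor_id == donor)
      e[, idx] <- e[, idx] - rowMeans(e[, idx, drop = FALSE])
    }
    dimnames(e) <- list(probes, co$sample_id)
    e + outer(rep(1, 20), 0.3 * as.numeric(co$mood_disorder))
  })
  stats <- fit_cpg_mixed(m, co)
  expect_true(all(stats$variance_ratio == 0))

  co$sexn <- as.numeric(co$sex == "male")
  for (pid in probes[c(1, 7, 13)]) {
    ols <- lm(m[pid, co$sample_id] ~ co$mood_disorder + co$age + co$sexn + co$region)
    sm <- summary(ols)$coefficients
    row <- stats[stats$probe_id == pid, ]
    expect_equal(row$effect, sm["co$mood_disorderTRUE", "Estimate"], tolerance = 1e-6)
    # same t statistic as the fixed-effect fit (only the df convention differs)
    t_ols <- sm["co$mood_disorderTRUE", "t value"]
    expect_equal(row$t_stat, t_ols, tolerance = 1e-4)
  }
})

test_that("a known mood effect is recovered to within ten percent", {
  cfg <- sim_config(n_donors = 40, regions_per_donor = 2, p_mood = 0.5,
                    n_probes = 200, n_age_cpgs = 0, n_dmrs = 0, seed = 33)
  co <- simulate_cohort(cfg)
  meth <- simulate_methylation(co, cfg)
  m <- beta_to_m(meth$beta)
  auto <- meth$annotation$probe_id[meth$annotation$probe_class == "autosomal"]
  delta <- 0.8
  m[auto, co$mood_disorder] <- m[auto, co$mood_disorder] + delta
  stats <- fit_cpg_mixed(m[auto, ], co, meth$annotation)
  expect_equal(mean(stats$effect), delta, tolerance = 0.1)
})

test_that("the per-region fixed model matches closed-form OLS and guards its inputs", {
  co <- validate_cohort(tibble::tibble(
    sample_id = sprintf("s%d", 1:6), donor_id = sprintf("D%d", 1:6),
    age = c(50, 60, 70, 50, 60, 70),
    sex = rep(c("female", "male"), 3),
    diagnosis = c("MDD", "MDD", "MDD", "control", "control", "control"),
    region = "MFG"))
  # age and sex exactly balanced across groups -> mood coefficient is the
  # difference of group means
  m <- matrix(c(5, 6, 7, 2, 3, 4), 1, dimnames = list("p1", co$sample_id))
  stats <- fit_cpg_fixed(m, co)
  expect_equal(stats$effect, 3, tolerance = 1e-12)
  expect_equal(stats$df, 2)

  expect_error(fit_cpg_fixed(m[, 1:4, drop = FALSE], co[1:4, ]),
               class = "dmrpipe_insufficient_sample_error")
  two_regions <- co; two_regions$region[1] <- "STG"
  expect_error(fit_cpg_fixed(m, two_regions), class = "dmrpipe_design_error")
})

test_that("the genomic inflation factor is calibrated and detects inflation", {
  expect_equal(genomic_lambda(rep(0.5, 200))$lambda, 1)
  p_unif <- withr::with_seed(9, runif(10000))
  expect_gt(genomic_lambda(p_unif)$lambda, 0.97)
  expect_lt(genomic_lambda(p_unif)$lambda, 1.03)

  # doubling the chi-square statistics doubles lambda
  chisq <- qchisq(p_unif, 1, lower.tail = FALSE)
  p_infl <- pchisq(2 * chisq, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p_infl)$lambda, 2, tolerance = 0.05)

  expect_warning(genomic_lambda(runif(50)), "unreliable")
})

test_that("inflation adjustment follows the selected mode and preserves ranking", {
  stats <- tibble::tibble(p = c(0.01, 0.2, 0.6, 0.001), p_adjusted = NA_real_)
  lam1 <- structure(list(lambda = 1, n_tests = 4, reliable = TRUE),
                    class = "inflation_estimate")
  for (mode in c("multiply_p", "genomic_control")) {
    out <- inflation_adjust(stats, lam1, mode)
    expect_equal(out$p_adjusted, stats$p)
  }

  out <- inflation_adjust(stats, 1.2, "multiply_p")
  expect_equal(out$p_adjusted[1], 0.012)
  expect_equal(order(out$p_adjusted), order(stats$p))
  expect_true(all(out$p_adjusted >= stats$p))

  # chi-square tail oracle: p = 0.01 -> chisq 6.6349; /2 -> 3.3174
  out_gc <- inflation_adjust(stats, 2, "genomic_control")
  expect_equal(out_gc$p_adjusted[1],
               pchisq(qchisq(0.99, 1) / 2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(out_gc$p_adjusted[1], 0.0685, tolerance = 1e-3)

  # deflation is left alone
  out_defl <- inflation_adjust(stats, 0.8, "multiply_p")
  expect_equal(out_defl$p_adjusted, stats$p)
})

test_that("per-CpG mixed p values are roughly calibrated on a null cohort", {
  cfg <- sim_config(n_donors = 40, regions_per_donor = 2, p_mood = 0.5,
                    n_probes = 800, n_age_cpgs = 0, n_dmrs = 0, seed = 35)
  co <- simulate_cohort(cfg)
  meth <- simulate_methylation(co, cfg)
  m <- beta_to_m(meth$beta)
  auto <- meth$annotation$probe_id[meth$annotation$probe_class == "autosomal"]
  stats <- fit_cpg_mixed(m[auto, ], co, meth$annotation)
  expect_gt(mean(stats$p < 0.05), 0.025)
  expect_lt(mean(stats$p < 0.05), 0.075)
  lam <- genomic_lambda(stats$p)
  expect_gt(lam$lambda, 0.9)
  expect_lt(lam$lambda, 1.1)
})

test_that("design guards reject unusable cohorts", {
  d <- small_dataset()
  m <- beta_to_m(d$beta)[auto_probes(d), ][1:5, , drop = FALSE]
  one_group <- d$cohort
  one_group$diagnosis <- "control"
  one_group$mood_disorder <- NULL
  expect_error(fit_cpg_mixed(m, one_group), class = "dmrpipe_design_error")
})
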