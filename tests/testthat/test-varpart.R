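make_m <- function(values, probes, samples) {
  matrix(values, length(probes), length(samples),
         dimnames = list(probes, samples))
}

test_that("residualize removes the requested covariates exactly", {
  cohort <- validate_cohort(tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    donor_id = sprintf("D%02d", 1:10),
    age = seq(30, 90, length.out = 10),
    sex = rep(c("female", "male"), 5),
    diagnosis = "control", region = "MFG"))
  m <- make_m(0, sprintf("p%d", 1:3), cohort$sample_id)
  m[1, ] <- 2 * cohort$age
  m[2, ] <- 5 + as.numeric(cohort$sex == "male")
  m[3, ] <- withr::with_seed(1, rnorm(10))

  # no covariates: per-probe centering
  centered <- residualize(m, cohort, character(0))
  expect_equal(centered, m - rowMeans(m), ignore_attr = TRUE)

  res <- residualize(m, cohort, c("age", "sex"))
  expect_lt(abs(cor(res[1, ], cohort$age)), 1e-10)
  expect_lt(max(abs(res[2, ])), 1e-10)

  single_sex <- cohort; single_sex$sex <- "female"
  expect_error(residualize(m, single_sex, "sex"), class = "dmrpipe_design_error")
})

test_that("pca_top returns descending variances and reconstructs the input", {
  probes <- sprintf("p%02d", 1:50)
  samples <- sprintf("s%02d", 1:10)
  m <- withr::with_seed(2, make_m(rnorm(500), probes, samples))

  pca <- pca_top(m, K = 9)
  expect_true(all(diff(pca$component_variances) <= 1e-12))
  expect_lte(sum(pca$component_variances), pca$total_variance + 1e-8)

  # full-rank reconstruction: scores x rotation recovers the centered input
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  recon <- t(pc$x %*% t(pc$rotation)) + rowMeans(m)
  expect_equal(recon, m, tolerance = 1e-8, ignore_attr = TRUE)

  # rank-1 input: first component carries everything
  r1 <- outer(withr::with_seed(3, rnorm(50)), seq_len(10))
  dimnames(r1) <- list(probes, samples)
  p1 <- pca_top(r1, K = 5)
  expect_gt(p1$component_variances[1] / p1$total_variance, 1 - 1e-10)

  # duplicated sample columns give identical scores
  dup <- cbind(m, dup1 = m[, 1]); colnames(dup)[11] <- "dup1"
  pd <- pca_top(dup, K = 5)
  expect_equal(pd$scores["s01", ], pd$scores["dup1", ], tolerance = 1e-8)

  expect_error(pca_top(m, K = 10), class = "dmrpipe_parameter_error")
})

test_that("per-PC ANOVA fractions match hand-computed cases and the permutation null", {
  cohort <- validate_cohort(tibble::tibble(
    sample_id = sprintf("s%d", 1:4), donor_id = sprintf("D%d", 1:4),
    age = c(40, 50, 60, 70), sex = "female", diagnosis = "control",
    region = c("MFG", "MFG", "STG", "STG")))
  pca <- structure(list(
    scores = matrix(c(1, 1, -1, -1, 2, 0, -2, 0), 4,
                    dimnames = list(cohort$sample_id, c("PC1", "PC2"))),
    component_variances = c(2, 1), total_variance = 3, K = 2),
    class = "meth_pca")
  fr <- per_pc_anova(pca, cohort, "region")
  expect_equal(unname(fr), c(1, 0.5))

  expect_error(per_pc_anova(pca, dplyr::mutate(cohort, region = "MFG"), "region"),
               class = "dmrpipe_degenerate_error")

  # permutation null: E[SS_between/SS_total] = (g - 1)/(n - 1)
  n <- 24; g <- 4
  scores <- withr::with_seed(4, matrix(rnorm(n), n, 1))
  pca_n <- structure(list(scores = scores, component_variances = 1,
                          total_variance = 1, K = 1), class = "meth_pca")
  fracs <- withr::with_seed(5, replicate(400, {
    co <- tibble::tibble(
      sample_id = sprintf("s%d", 1:n), donor_id = sprintf("D%d", 1:n),
      age = 50, sex = "female", diagnosis = "control",
      region = sample(rep(c("MFG", "STG", "SVZ", "THA"), n / g)))
    per_pc_anova(pca_n, co, "region")
  }))
  expect_equal(mean(fracs), (g - 1) / (n - 1), tolerance = 0.02)
})

test_that("aggregation weights fractions by component variance and is scale-free", {
  pca <- structure(list(scores = NULL, component_variances = c(3, 1),
                        total_variance = 4, K = 2), class = "meth_pca")
  expect_equal(aggregate_fractions(pca, c(1, 0)), 75)
  expect_equal(aggregate_fractions(pca, c(0, 0)), 0)
  expect_equal(aggregate_fractions(pca, c(1, 1)), 100)
  scaled <- pca; scaled$component_variances <- pca$component_variances * 7
  expect_equal(aggregate_fractions(scaled, c(0.3, 0.9)),
               aggregate_fractions(pca, c(0.3, 0.9)))
})

test_that("sequential-mode fractions sum to one with the residual", {
  d <- small_dataset()
  m <- beta_to_m(d$beta)[auto_probes(d), ]
  vp <- variance_partition(m, d$cohort, factors = c("region", "mood_disorder"),
                           adjust = c("age", "sex"), K = 10, mode = "sequential")
  sums <- vp$per_pc |>
    dplyr::group_by(pc) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 10), tolerance = 1e-10)
  expect_true("residual" %in% vp$per_pc$factor)

  g <- glance(vp)
  expect_true(all(c("percent_region", "percent_residual", "k") %in% names(g)))
  td <- tidy(vp)
  expect_equal(nrow(td), 10 * 3)
})

test_that("classical MDS embeds exactly in easy geometries", {
  probes <- sprintf("p%02d", 1:30)
  base <- withr::with_seed(6, rnorm(30))
  m <- outer(base, c(1, 2, 3)); dimnames(m) <- list(probes, c("a", "b", "c"))
  mds <- classical_mds(m, n_dims = 2, top_probes = 30)
  # collinear configuration: first axis reproduces the 1-D geometry
  expect_gt(abs(cor(mds$MDS1, c(1, 2, 3))), 1 - 1e-10)
  expect_true(attr(mds, "reduced"))

  m2 <- withr::with_seed(7, matrix(rnorm(30 * 6), 30,
                                   dimnames = list(probes, sprintf("s%d", 1:6))))
  m2 <- cbind(m2, s6dup = m2[, 6])
  mds2 <- classical_mds(m2, n_dims = 2, top_probes = 30)
  expect_equal(unlist(mds2[6, -1]), unlist(mds2[7, -1]), tolerance = 1e-8,
               ignore_attr = TRUE)

  # full-dimension embedding preserves all pairwise distances
  mds_full <- classical_mds(m2[, 1:6], n_dims = 5, top_probes = 30)
  d_in <- dist(t(m2[, 1:6]))
  d_out <- dist(as.matrix(mds_full[, -1]))
  expect_equal(as.vector(d_out), as.vector(d_in), tolerance = 1e-8)
})
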