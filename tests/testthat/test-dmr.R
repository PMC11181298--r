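test_that("the ACF of the p-value track is near zero under independence", {
  p <- withr::with_seed(11, runif(10000))
  stats <- toy_stats(p, pos = cumsum(rep(60L, 10000)))
  acf <- estimate_acf(stats, max_dist = 600, bin_width = 100)
  expect_true(all(abs(acf$correlation) < 0.05))
  expect_true(all(acf$correlation_used >= 0 & acf$correlation_used <= 1))
})

test_that("a duplicated p-value track yields first-bin correlation near one", {
  p_half <- withr::with_seed(12, runif(300))
  # consecutive probe pairs 1 bp apart share the same p value
  p <- rep(p_half, each = 2)
  pos <- as.vector(rbind(seq(1000, by = 2000, length.out = 300),
                         seq(1001, by = 2000, length.out = 300)))
  acf <- estimate_acf(toy_stats(p, pos = pos), max_dist = 300, bin_width = 100)
  expect_gt(acf$correlation[1], 0.99)
})

test_that("the generator's spatial correlation shows up as a decaying ACF", {
  cfg <- sim_config(n_donors = 30, regions_per_donor = 2, p_mood = 0.5,
                    n_probes = 3000, n_age_cpgs = 0, n_dmrs = 0,
                    donor_sd = 0, region_sd = 0, acf_decay = 600,
                    probe_spacing_mean = 150, seed = 13)
  co <- simulate_cohort(cfg)
  meth <- simulate_methylation(co, cfg)
  m <- beta_to_m(meth$beta)
  auto <- meth$annotation$probe_id[meth$annotation$probe_class == "autosomal"]
  stats <- fit_cpg_mixed(m[auto, ], co, meth$annotation)
  acf <- estimate_acf(stats, max_dist = 1000, bin_width = 200, p_col = "p")
  # noise is the only variance component, so z correlation tracks exp(-d/600)
  expect_gt(acf$correlation[1], 0.3)
  expect_lt(acf$correlation[5], acf$correlation[1])
  expect_gt(sum(diff(acf$correlation) < 0), 2)
})

test_that("Stouffer-Liptak reduces to known closed forms", {
  expect_equal(stouffer_liptak(0.123, matrix(1))$p, 0.123, tolerance = 1e-12)

  sl <- stouffer_liptak(c(0.05, 0.05))
  z <- 2 * qnorm(0.95) / sqrt(2)
  expect_equal(sl$z, z, tolerance = 1e-12)
  expect_equal(sl$p, pnorm(z, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(sl$p, 0.0100, tolerance = 1e-3)

  # perfect dependence: combining identical p values changes nothing
  ones <- matrix(1, 3, 3)
  expect_equal(stouffer_liptak(rep(0.05, 3), ones)$p, 0.05, tolerance = 1e-12)

  # identity-correlation case equals the textbook Stouffer formula
  p <- c(0.01, 0.2, 0.5, 0.03)
  direct <- pnorm(sum(qnorm(1 - p)) / 2, lower.tail = FALSE)
  expect_equal(stouffer_liptak(p)$p, direct, tolerance = 1e-12)

  # non-PSD input is repaired and flagged
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  res <- stouffer_liptak(c(0.1, 0.1, 0.1), bad)
  expect_true(res$repaired)
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("the candidate scan finds exactly the constructed region", {
  p <- c(rep(0.9, 10), rep(0.001, 5), rep(0.9, 10))
  stats <- toy_stats(p, pos = seq_along(p) * 100L)
  regions <- find_candidate_regions(stats, seed_p = 0.05, max_gap = 500,
                                    min_probes = 3)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$n_probes, 5)
  expect_equal(regions$start, 1100L)
  expect_equal(regions$end, 1500L)

  none <- find_candidate_regions(toy_stats(rep(0.5, 50)))
  expect_equal(nrow(none), 0)
})

test_that("the scanner agrees with a connected-components oracle on random tracks", {
  # oracle: graph over sub-threshold probes, edge when within max_gap;
  # candidate regions are the connected components with >= min_probes
  oracle_regions <- function(stats, seed_p, max_gap, min_probes) {
    sig <- which(stats$p_adjusted < seed_p)
    if (length(sig) == 0) return(list())
    comp <- seq_along(sig)
    for (a in seq_along(sig)) {
      for (b in seq_along(sig)) {
        if (stats$chrom[sig[a]] == stats$chrom[sig[b]] &&
            abs(stats$pos[sig[a]] - stats$pos[sig[b]]) <= max_gap) {
          old <- comp[b]; comp[comp == old] <- comp[a]
        }
      }
    }
    comps <- unname(split(sig, comp))
    comps <- comps[vapply(comps, length, 1L) >= min_probes]
    comps[order(vapply(comps, min, 1L))]
  }
  for (seed in 14:16) {
    p <- withr::with_seed(seed, runif(200)^2)
    pos <- withr::with_seed(seed + 100, cumsum(sample(c(50L, 200L, 600L), 200,
                                                      replace = TRUE)))
    stats <- toy_stats(p, pos = pos)
    got <- find_candidate_regions(stats, 0.1, 400, 3)
    want <- oracle_regions(stats, 0.1, 400, 3)
    expect_equal(nrow(got), length(want))
    expect_equal(got$probe_idx, want, ignore_attr = TRUE)
  }
})

test_that("region scoring handles the identity and full-dependence limits", {
  acf0 <- estimate_acf(toy_stats(withr::with_seed(17, runif(500))),
                       max_dist = 500, bin_width = 100)
  stats <- toy_stats(c(0.9, 0.02, 0.9), pos = c(100L, 5000L, 9000L))
  win <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5000L,
                        n_probes = 1L, probe_idx = list(2L))
  scored <- score_regions(win, stats, acf0)
  expect_equal(scored$p_region, 0.02, tolerance = 1e-12)
  expect_equal(scored$mean_effect, 1)

  # all-ones correlation: combined p equals the shared p
  acf1 <- tibble::tibble(bin_lo = 0, bin_hi = 1000, correlation = 1,
                         correlation_used = 1, n_pairs = 100L)
  stats2 <- toy_stats(rep(0.03, 4), pos = c(100L, 200L, 300L, 400L))
  win2 <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L,
                         n_probes = 4L, probe_idx = list(1:4))
  expect_equal(score_regions(win2, stats2, acf1)$p_region, 0.03,
               tolerance = 1e-12)
})

test_that("Sidak correction is exact on a grid and monotone in both arguments", {
  expect_equal(1 - (1 - 0.01)^5, 0.04901, tolerance = 1e-4)
  stats <- toy_stats(rep(0.5, 100), pos = seq(0, by = 200L, length.out = 100))
  grid <- expand.grid(p = c(0, 1e-6, 1e-3, 0.01, 0.1, 0.5, 0.99),
                      width = c(100, 500, 2000, 20000))
  covered <- 100 * 200
  prev_by_width <- list()
  for (i in seq_len(nrow(grid))) {
    dmr <- tibble::tibble(chrom = "chr1", start = 1000L,
                          end = as.integer(1000 + grid$width[i] - 1),
                          n_probes = 3L, p_region = grid$p[i])
    out <- sidak_correct(dmr, stats)
    k <- max(1, covered / grid$width[i])
    expect_equal(out$p_sidak, 1 - (1 - grid$p[i])^k, tolerance = 1e-9)
    expect_equal(out$k_effective, k)
  }
  # monotone in p_region at fixed k and in k at fixed p_region
  ps <- sort(unique(grid$p))
  dmrs <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1499L,
                         n_probes = 3L, p_region = ps)
  out <- sidak_correct(dmrs, stats)
  expect_true(all(diff(out$p_sidak) >= 0))
  widths <- c(20000L, 2000L, 500L, 100L)  # decreasing width -> increasing k
  dmrs_k <- tibble::tibble(chrom = "chr1", start = 1000L,
                           end = 1000L + widths - 1L,
                           n_probes = 3L, p_region = 0.01)
  out_k <- sidak_correct(dmrs_k, stats)
  expect_true(all(diff(out_k$k_effective) > 0))
  expect_true(all(diff(out_k$p_sidak) >= 0))
})

test_that("DMR annotation uses the majority gene with a lexicographic tie rule", {
  stats <- toy_stats(rep(0.01, 4), pos = c(100L, 200L, 300L, 400L))
  ann <- tibble::tibble(
    probe_id = stats$probe_id, chrom = "chr1", pos = stats$pos,
    probe_class = "autosomal",
    gene = c("ZEB1", "ZEB1", "ABC1", "ABC1"),
    promoter = c(FALSE, TRUE, FALSE, FALSE))
  dmr <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L,
                        n_probes = 4L, probe_idx = list(1:4))
  out <- annotate_dmrs(dmr, stats, ann)
  expect_equal(out$gene, "ABC1")      # tie -> lexicographically first
  expect_true(out$gene_tie)
  expect_true(out$promoter)

  ann2 <- ann; ann2$gene <- NA_character_; ann2$promoter <- FALSE
  out2 <- annotate_dmrs(dmr, stats, ann2)
  expect_true(is.na(out2$gene))
  expect_false(out2$promoter)
  expect_false(out2$gene_tie)
})

test_that("end-to-end calling recovers an injected region and annotates it", {
  d <- powered_dataset()
  m <- beta_to_m(d$beta)[auto_probes(d), ]
  stats <- fit_cpg_mixed(m, d$cohort, d$annotation)
  stats <- inflation_adjust(stats, genomic_lambda(stats$p))
  dmrs <- call_dmrs(stats, d$annotation)
  expect_s3_class(dmrs, "dmr_table")
  sig <- dmrs[dmrs$significant, ]
  tr <- d$truth$true_dmr_intervals
  hits <- vapply(seq_len(nrow(tr)), function(j) {
    any(sig$start <= tr$end[j] & sig$end >= tr$start[j])
  }, logical(1))
  expect_gt(mean(hits), 0.4)
  expect_true(all(sig$gene %in% tr$gene))
  expect_true(all(sig$promoter))
})
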