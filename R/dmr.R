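# Region calling from the per-CpG p-value track: autocorrelation estimation,
# Stouffer-Liptak combination, candidate-region scan, Sidak correction.

# z-transform with clipping so boundary p values stay finite
p_to_z <- function(p) {
  qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
}

check_sorted <- function(stats) {
  o <- order(stats$chrom, stats$pos)
  if (!identical(o, seq_len(nrow(stats)))) {
    abort_dmrpipe("CpG statistics must be sorted by (chrom, pos)",
                  "dmrpipe_ordering_error")
  }
  invisible(stats)
}

#' Distance-binned autocorrelation of the p-value track
#'
#' For each genomic-distance bin, the Pearson correlation of the
#' z-transformed p values (`z = qnorm(1 - p)`) over all probe pairs on the
#' same chromosome whose distance falls in the bin `(lo, hi]`. Bins with
#' fewer than `min_pairs` pairs inherit the previous bin's estimate (0 for
#' the first bin).
#'
#' @param stats CpG statistics tibble sorted by `(chrom, pos)` with columns
#'   `chrom`, `pos` and the p-value column `p_col`.
#' @param max_dist Maximum distance considered (bp), default 1000.
#' @param bin_width Bin width (bp), default 100.
#' @param p_col Column holding the p values, default `"p_adjusted"`.
#' @param min_pairs Minimum pairs per bin for a usable estimate, default 50.
#' @return A tibble of class `acf_estimate`: `bin_lo`, `bin_hi`,
#'   `correlation` (raw), `correlation_used` (clipped to \[0, 1\]),
#'   `n_pairs`.
#' @export
estimate_acf <- function(stats, max_dist = 1000, bin_width = 100,
                         p_col = "p_adjusted", min_pairs = 50) {
  check_sorted(stats)
  z <- p_to_z(stats[[p_col]])
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1

  # collect pairs per chromosome: probes are sorted, distances bounded, so a
  # forward scan with a sliding right end suffices
  zi <- list(); zj <- list(); dd <- list()
  for (ch in unique(stats$chrom)) {
    sel <- which(stats$chrom == ch)
    pos <- stats$pos[sel]
    zc <- z[sel]
    n <- length(sel)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && pos[j] - pos[i] <= max_dist) j <- j + 1
      if (j > i + 1) {
        rng <- (i + 1):(j - 1)
        zi[[length(zi) + 1]] <- rep(zc[i], length(rng))
        zj[[length(zj) + 1]] <- zc[rng]
        dd[[length(dd) + 1]] <- pos[rng] - pos[i]
      }
    }
  }
  zi <- unlist(zi); zj <- unlist(zj); dd <- unlist(dd)
  bin <- if (length(dd)) pmin(ceiling(dd / bin_width), nb) else integer(0)

  correlation <- n_pairs <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- which(bin == b)
    n_pairs[b] <- length(sel)
    correlation[b] <- if (length(sel) >= 2 &&
                          sd(zi[sel]) > 0 && sd(zj[sel]) > 0) {
      cor(zi[sel], zj[sel])
    } else NA_real_
  }
  used <- numeric(nb)
  prev <- 0
  for (b in seq_len(nb)) {
    if (n_pairs[b] >= min_pairs && is.finite(correlation[b])) {
      prev <- min(max(correlation[b], 0), 1)
    }
    used[b] <- prev
  }
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        correlation = correlation, correlation_used = used,
                        n_pairs = as.integer(n_pairs))
  class(out) <- c("acf_estimate", class(out))
  out
}

# correlation for a vector of pair distances from a binned ACF; 0 beyond max
acf_lookup <- function(acf, dist) {
  out <- numeric(length(dist))
  inside <- dist > 0 & dist <= max(acf$bin_hi)
  idx <- findInterval(dist[inside], acf$bin_lo, left.open = TRUE)
  out[inside] <- acf$correlation_used[idx]
  out[dist == 0] <- 1
  out
}

#' Stouffer-Liptak combination of correlated p values
#'
#' `z_i = qnorm(1 - p_i)`; the combined statistic is
#' `sum(z) / sqrt(sum(corr))` and the combined p its upper normal tail. With
#' an identity correlation matrix this is the classical Stouffer
#' combination. A correlation matrix that is not positive semidefinite
#' (after clipping) is repaired by flooring its eigenvalues at zero.
#'
#' @param p Numeric vector of p values in (0, 1).
#' @param corr Correlation matrix (defaults to identity).
#' @return A list: `p` (combined), `z`, `repaired` (TRUE if a nearest-PSD
#'   repair was applied).
#' @export
stouffer_liptak <- function(p, corr = diag(length(p))) {
  k <- length(p)
  stopifnot(nrow(corr) == k, ncol(corr) == k)
  repaired <- FALSE
  if (k > 1) {
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      eg <- eigen(corr, symmetric = TRUE)
      corr <- eg$vectors %*% diag(pmax(eg$values, 0)) %*% t(eg$vectors)
      repaired <- TRUE
    }
  }
  z <- p_to_z(p)
  denom <- sqrt(sum(corr))
  zc <- sum(z) / denom
  list(p = pnorm(zc, lower.tail = FALSE), z = zc, repaired = repaired)
}

#' Scan the p-value track for candidate regions
#'
#' Deterministic left-to-right scan: probes with `p < seed_p` are chained
#' whenever consecutive sub-threshold probes are at most `max_gap` bp apart;
#' chains with at least `min_probes` probes are candidate regions. Merging
#' of nearby chains is implicit in the gap rule.
#'
#' @inheritParams estimate_acf
#' @param seed_p Seed/extension threshold, default 0.05.
#' @param max_gap Maximum gap between member probes (bp), default 500.
#' @param min_probes Minimum probes per region, default 3.
#' @return A tibble with one row per candidate: `chrom`, `start`, `end`
#'   (1-based inclusive probe positions), `n_probes`, `probe_idx` (list of
#'   row indices into `stats`).
#' @export
find_candidate_regions <- function(stats, seed_p = 0.05, max_gap = 500,
                                   min_probes = 3, p_col = "p_adjusted") {
  check_sorted(stats)
  p <- stats[[p_col]]
  hits <- which(p < seed_p & is.finite(p))
  if (length(hits) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          probe_idx = list()))
  }
  chrom <- stats$chrom[hits]
  pos <- stats$pos[hits]
  new_chain <- c(TRUE, diff(pos) > max_gap | chrom[-1] != chrom[-length(chrom)])
  chain <- cumsum(new_chain)
  purrr::map_dfr(split(hits, chain), function(idx) {
    tibble::tibble(chrom = stats$chrom[idx[1]],
                   start = as.integer(min(stats$pos[idx])),
                   end = as.integer(max(stats$pos[idx])),
                   n_probes = length(idx),
                   probe_idx = list(idx))
  }) |>
    dplyr::filter(.data$n_probes >= min_probes) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Score candidate regions by Stouffer-Liptak combination
#'
#' Builds each region's probe-pair correlation matrix from the binned ACF
#' (distance lookup, 0 beyond the last bin) and combines the member p values.
#'
#' @param windows Candidate regions from [find_candidate_regions()].
#' @param stats The CpG statistics the windows index into.
#' @param acf An [estimate_acf()] result.
#' @inheritParams estimate_acf
#' @return A DMR tibble: `region_id`, `chrom`, `start`, `end`, `n_probes`,
#'   `p_region`, `mean_effect`, `psd_repaired`, `probe_idx`.
#' @export
score_regions <- function(windows, stats, acf, p_col = "p_adjusted") {
  scored <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    idx <- windows$probe_idx[[i]]
    pos <- stats$pos[idx]
    dmat <- abs(outer(pos, pos, "-"))
    corr <- matrix(acf_lookup(acf, as.vector(dmat)), length(pos))
    diag(corr) <- 1
    sl <- stouffer_liptak(stats[[p_col]][idx], corr)
    tibble::tibble(p_region = sl$p,
                   mean_effect = mean(stats$effect[idx], na.rm = TRUE),
                   psd_repaired = sl$repaired)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("dmr_%03d", seq_len(nrow(windows)))),
    dplyr::select(windows, "chrom", "start", "end", "n_probes"),
    scored)
  out$probe_idx <- windows$probe_idx
  out
}

#' Sidak multiple-testing correction for regions
#'
#' The effective number of tests for a region is
#' `k = max(1, covered_bases / region_width)` where `covered_bases` is
#' approximated by (number of tested probes) x (median inter-probe spacing)
#' genome-wide, and the region width is `end - start + 1` (floored at 1 bp).
#' `p_sidak = 1 - (1 - p_region)^k`.
#'
#' @param dmrs DMR tibble with `p_region` filled.
#' @param stats The full CpG statistics table (defines the covered bases).
#' @param alpha Significance level for the `significant` flag, default 0.05.
#' @return `dmrs` with `k_effective`, `p_sidak` and `significant` filled.
#' @export
sidak_correct <- function(dmrs, stats, alpha = 0.05) {
  spacing <- stats |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(d = .data$pos - dplyr::lag(.data$pos)) |>
    dplyr::pull(.data$d)
  med_spacing <- median(spacing, na.rm = TRUE)
  covered <- nrow(stats) * med_spacing
  width <- pmax(1, dmrs$end - dmrs$start + 1)
  k <- pmax(1, covered / width)
  # 1 - (1-p)^k computed via expm1/log1p for small p_region
  p_sidak <- -expm1(k * log1p(-pmin(dmrs$p_region, 1 - 1e-16)))
  dmrs$k_effective <- k
  dmrs$p_sidak <- pmin(1, pmax(0, p_sidak))
  dmrs$p_sidak[dmrs$p_region == 0] <- 0
  dmrs$significant <- dmrs$p_sidak < alpha
  dmrs
}

#' Annotate DMRs with gene symbols and promoter status
#'
#' Gene = majority gene symbol among member probes (ties broken
#' lexicographically and flagged); promoter = TRUE iff any member probe is a
#' promoter probe.
#'
#' @param dmrs DMR tibble with `probe_idx`.
#' @param stats CpG statistics the indices refer to.
#' @param annotation Probe annotation tibble.
#' @return `dmrs` with `gene`, `promoter`, `gene_tie` filled.
#' @export
annotate_dmrs <- function(dmrs, stats, annotation) {
  ann <- annotation[match(stats$probe_id, annotation$probe_id), ]
  info <- purrr::map_dfr(dmrs$probe_idx, function(idx) {
    genes <- ann$gene[idx]
    genes <- genes[!is.na(genes) & genes != ""]
    if (length(genes) == 0) {
      return(tibble::tibble(gene = NA_character_, promoter = FALSE,
                            gene_tie = FALSE))
    }
    tab <- sort(table(genes), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    tibble::tibble(gene = sort(top)[1],
                   promoter = any(ann$promoter[idx], na.rm = TRUE),
                   gene_tie = length(top) > 1)
  })
  dplyr::bind_cols(dmrs, info)
}

#' Call differentially methylated regions
#'
#' End-to-end region calling from a per-CpG statistics table: ACF estimation
#' on the (inflation-adjusted) p-value track, candidate scan, Stouffer-Liptak
#' scoring, Sidak correction and (optionally) gene annotation.
#'
#' @inheritParams find_candidate_regions
#' @inheritParams sidak_correct
#' @param annotation Optional probe annotation for [annotate_dmrs()].
#' @param max_dist,bin_width Passed to [estimate_acf()].
#' @return A DMR tibble of class `dmr_table` sorted by `(chrom, start)`;
#'   attribute `acf` holds the ACF estimate.
#' @export
call_dmrs <- function(stats, annotation = NULL, seed_p = 0.05, max_gap = 500,
                      min_probes = 3, alpha = 0.05, max_dist = 1000,
                      bin_width = 100, p_col = "p_adjusted") {
  check_sorted(stats)
  acf <- estimate_acf(stats, max_dist, bin_width, p_col)
  windows <- find_candidate_regions(stats, seed_p, max_gap, min_probes, p_col)
  if (nrow(windows) == 0) {
    out <- tibble::tibble(
      region_id = character(), chrom = character(), start = integer(),
      end = integer(), n_probes = integer(), p_region = numeric(),
      mean_effect = numeric(), psd_repaired = logical(),
      probe_idx = list(), k_effective = numeric(), p_sidak = numeric(),
      significant = logical(), gene = character(), promoter = logical(),
      gene_tie = logical())
  } else {
    out <- score_regions(windows, stats, acf, p_col) |>
      sidak_correct(stats, alpha)
    if (!is.null(annotation)) {
      out <- annotate_dmrs(out, stats, annotation)
    } else {
      out$gene <- NA_character_
      out$promoter <- FALSE
      out$gene_tie <- FALSE
    }
    out <- dplyr::arrange(out, .data$chrom, .data$start)
  }
  attr(out, "acf") <- acf
  class(out) <- c("dmr_table", class(out))
  out
}
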