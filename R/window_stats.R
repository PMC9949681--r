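#' @keywords internal
#' Per-site Weir-Cockerham (1984) variance components for two groups.
#' Diploid genotypes are reconstructed from the two phased haplotypes of each
#' sample; a site is usable only if both groups have >= 2 samples with
#' complete genotypes.  Returns per-site numerator (a) and denominator
#' (a + b + c) of the ratio-of-sums estimator.
fst_site_components_wc <- function(panel, popmap, group_a, group_b,
                                   site_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(panel$sites))
  stats_for <- function(g) {
    samples <- popmap$sample[popmap$group == g]
    if (!length(samples)) stop("unknown or empty group: ", g)
    h1 <- panel$alleles[site_idx, paste0(samples, "_h1"), drop = FALSE]
    h2 <- panel$alleles[site_idx, paste0(samples, "_h2"), drop = FALSE]
    ok <- !is.na(h1) & !is.na(h2)
    n <- rowSums(ok)
    gsum <- rowSums((h1 + h2) * ok, na.rm = TRUE)
    hets <- rowSums((h1 != h2) * ok, na.rm = TRUE)
    list(n = n, p = ifelse(n > 0, gsum / (2 * n), NA_real_),
         h = ifelse(n > 0, hets / n, NA_real_))
  }
  A <- stats_for(group_a); B <- stats_for(group_b)
  usable <- A$n >= 2 & B$n >= 2
  r <- 2
  nbar <- (A$n + B$n) / 2
  nt <- A$n + B$n
  nc <- (nt - (A$n^2 + B$n^2) / nt) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / nt
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / nt
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  num <- ifelse(usable, a, NA_real_)
  den <- ifelse(usable, a + b + cc, NA_real_)
  data.frame(num = num, den = den, usable = usable)
}

#' @keywords internal
#' Hudson estimator per-site components (allele-count based).
fst_site_components_hudson <- function(panel, popmap, group_a, group_b,
                                       site_idx = NULL) {
  fq <- group_freqs(panel, popmap, c(group_a, group_b), site_idx)
  n1 <- fq$n[, 1]; n2 <- fq$n[, 2]
  p1 <- fq$p[, 1]; p2 <- fq$p[, 2]
  usable <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = ifelse(usable, num, NA_real_),
             den = ifelse(usable, den, NA_real_), usable = usable)
}

#' Windowed F_ST between two groups
#'
#' Weir-Cockerham (1984) estimator, combined over sites as a ratio of sums
#' (sum of the `a` components over the sum of `a + b + c`), matching the
#' windowed estimator of vcftools.  The Hudson estimator is available for
#' sensitivity analysis.  Returns `NA` (with a warning for an empty window)
#' when fewer than `min_sites` usable sites fall in the window.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap popmap data.frame.
#' @param group_a,group_b group labels.
#' @param window list or one-row data.frame with `contig`, `start`, `end`.
#' @param estimator `"wc"` (default) or `"hudson"`.
#' @param min_sites minimum usable sites per window (default 10).
#' @return scalar F_ST or `NA`.
#' @export
fst_window <- function(panel, popmap, group_a, group_b, window,
                       estimator = c("wc", "hudson"), min_sites = 10L) {
  estimator <- match.arg(estimator)
  idx <- sites_in_window(panel, window$contig, window$start, window$end)
  if (!length(idx)) {
    warning("empty window ", window$contig, ":", window$start, "-", window$end)
    return(NA_real_)
  }
  comp <- if (estimator == "wc")
    fst_site_components_wc(panel, popmap, group_a, group_b, idx)
  else fst_site_components_hudson(panel, popmap, group_a, group_b, idx)
  if (sum(comp$usable) < min_sites) return(NA_real_)
  sum(comp$num[comp$usable]) / sum(comp$den[comp$usable])
}

#' Windowed mean pairwise sequence divergence (d_XY)
#'
#' `(1 / window_length) * sum over sites of pA (1 - pB) + pB (1 - pA)`,
#' i.e. the per-bp probability that two sequences drawn from the two
#' populations differ; invariant sites contribute 0.
#'
#' @param pA,pB per-site allele frequencies of the two populations (`NA`
#'   frequencies are skipped).
#' @param window_length window length in bp (> 0).
#' @return per-bp divergence (0 when no sites).
#' @export
dxy_window <- function(pA, pB, window_length) {
  if (window_length <= 0) stop("window_length must be positive")
  ok <- !is.na(pA) & !is.na(pB)
  sum(pA[ok] * (1 - pB[ok]) + pB[ok] * (1 - pA[ok])) / window_length
}

abba_baba <- function(p1, p2, p3, pO) {
  list(abba = (1 - p1) * p2 * p3 * (1 - pO),
       baba = p1 * (1 - p2) * p3 * (1 - pO))
}

#' Patterson's D over a set of sites
#'
#' `sum(ABBA - BABA) / sum(ABBA + BABA)` with frequency-weighted
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`; frequencies
#' must already be polarized so the derived allele is counted (see
#' [polarized_freqs()]).
#'
#' @param p1,p2,p3,pO per-site derived-allele frequencies for (sister,
#'   recipient, donor, outgroup).
#' @return D in `[-1, 1]`, or `NA` when the denominator is 0.
#' @export
d_stat_window <- function(p1, p2, p3, pO) {
  ok <- !is.na(p1) & !is.na(p2) & !is.na(p3) & !is.na(pO)
  ab <- abba_baba(p1[ok], p2[ok], p3[ok], pO[ok])
  den <- sum(ab$abba + ab$baba)
  if (den == 0) return(NA_real_)
  sum(ab$abba - ab$baba) / den
}

#' f_d admixture-fraction estimator over a set of sites
#'
#' `f_d = S(P1, P2, P3, O) / S(P1, P_D, P_D, O)` where `S` is the
#' ABBA-minus-BABA sum and, site by site, `P_D` is whichever of P2/P3 has the
#' higher derived-allele frequency.  Reported `NA` when the window's D is
#' negative or the denominator is not positive (the estimator is only
#' meaningful for an excess of shared derived alleles).
#'
#' @inheritParams d_stat_window
#' @return f_d, or `NA`.
#' @export
fd_window <- function(p1, p2, p3, pO) {
  ok <- !is.na(p1) & !is.na(p2) & !is.na(p3) & !is.na(pO)
  p1 <- p1[ok]; p2 <- p2[ok]; p3 <- p3[ok]; pO <- pO[ok]
  if (!length(p1)) return(NA_real_)
  ab <- abba_baba(p1, p2, p3, pO)
  if (sum(ab$abba + ab$baba) == 0) return(NA_real_)
  d <- sum(ab$abba - ab$baba) / sum(ab$abba + ab$baba)
  if (d < 0) return(NA_real_)
  pd <- pmax(p2, p3)
  abd <- abba_baba(p1, pd, pd, pO)
  den <- sum(abd$abba - abd$baba)
  if (den <= 0) return(NA_real_)
  sum(ab$abba - ab$baba) / den
}

#' Outgroup-polarized derived-allele frequencies
#'
#' The outgroup consensus allele is taken as ancestral: at sites where the
#' outgroup alternate-allele frequency exceeds 0.5 all frequencies are
#' flipped.  Sites where the outgroup is substantially polymorphic (frequency
#' in (0.1, 0.9)) are excluded, as are sites with missing group frequencies.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap popmap data.frame.
#' @param groups character(4): P1 (sister), P2 (recipient), P3 (donor),
#'   outgroup.
#' @param site_idx site rows (default all).
#' @return matrix with columns `p1`, `p2`, `p3`, `pO` and attribute
#'   `site_idx` giving the retained rows.
#' @export
polarized_freqs <- function(panel, popmap, groups, site_idx = NULL) {
  stopifnot(length(groups) == 4)
  if (is.null(site_idx)) site_idx <- seq_len(nrow(panel$sites))
  fq <- group_freqs(panel, popmap, groups, site_idx)
  p <- fq$p
  pO <- p[, 4]
  keep <- !is.na(pO) & !(pO > 0.1 & pO < 0.9) &
    stats::complete.cases(p) & fq$n[, 4] >= 2
  p <- p[keep, , drop = FALSE]
  flip <- p[, 4] > 0.5
  p[flip, ] <- 1 - p[flip, ]
  colnames(p) <- c("p1", "p2", "p3", "pO")
  attr(p, "site_idx") <- site_idx[keep]
  p
}

#' Z-transform a per-window statistic and assign Normal-tail P values
#'
#' `z = (x - mean) / sd` over the non-NA windows, with P from the standard
#' Normal: two-tailed (used for f_d) or upper one-tailed (used for the F_ST
#' selection scan).  Windows are flagged significant at `P < p_cut`
#' (default 0.001).  A constant vector yields a warning and all P = 1.
#'
#' @param values numeric vector of per-window statistics (may contain NA).
#' @param tail `"two"` or `"upper"`.
#' @param p_cut significance level (default 0.001).
#' @return data.frame with columns `z`, `p`, `sig` aligned with `values`.
#' @export
z_scan <- function(values, tail = c("two", "upper"), p_cut = 0.001) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-NA windows")
  mu <- mean(values[ok]); sdv <- stats::sd(values[ok])
  if (sdv == 0) {
    warning("constant statistic: all P set to 1")
    z <- ifelse(ok, 0, NA_real_)
    p <- ifelse(ok, 1, NA_real_)
  } else {
    z <- (values - mu) / sdv
    p <- if (tail == "two") 2 * stats::pnorm(-abs(z)) else
      stats::pnorm(z, lower.tail = FALSE)
  }
  data.frame(z = z, p = p, sig = !is.na(p) & p < p_cut)
}

#' Windowed introgression/differentiation scan
#'
#' Computes, for every sliding window: usable site count, F_ST between
#' `fst_groups` (default P2 vs P3), per-bp d_XY between the same pair,
#' Patterson's D and f_d for (P1, P2; P3, outgroup), then Z-scores and P
#' values (two-tailed for f_d, upper-tailed for F_ST) across windows.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap popmap data.frame.
#' @param p1,p2,p3,outgroup group labels: sister (non-introgressed reference),
#'   recipient, donor, outgroup.
#' @param fst_groups character(2), the F_ST/d_XY pair (default `c(p2, p3)`).
#' @param size,step window size and step in bp.
#' @param min_sites minimum usable sites per window.
#' @param estimator F_ST estimator (see [fst_window()]).
#' @param p_cut significance level for the Z tests.
#' @return data.frame: one row per window with columns `contig`, `start`,
#'   `end`, `clipped`, `n_sites`, `fst`, `dxy`, `d`, `fd`, `z_fd`, `p_fd`,
#'   `sig_fd`, `z_fst`, `p_fst`, `sig_fst`.
#' @export
scan_windows <- function(panel, popmap, p1, p2, p3, outgroup,
                         fst_groups = c(p2, p3), size = 50000L, step = 20000L,
                         min_sites = 10L, estimator = "wc", p_cut = 0.001) {
  validate_popmap(panel, popmap)
  wins <- iterate_windows(stats::setNames(panel$contigs$length,
                                          panel$contigs$contig), size, step)
  comp <- if (estimator == "wc")
    fst_site_components_wc(panel, popmap, fst_groups[1], fst_groups[2])
  else fst_site_components_hudson(panel, popmap, fst_groups[1], fst_groups[2])
  fq_pair <- group_freqs(panel, popmap, fst_groups)
  pol <- polarized_freqs(panel, popmap, c(p1, p2, p3, outgroup))
  pol_idx <- attr(pol, "site_idx")
  n <- nrow(wins)
  out <- data.frame(wins, n_sites = 0L, fst = NA_real_, dxy = NA_real_,
                    d = NA_real_, fd = NA_real_)
  for (i in seq_len(n)) {
    idx <- sites_in_window(panel, wins$contig[i], wins$start[i], wins$end[i])
    usable <- idx[comp$usable[idx]]
    out$n_sites[i] <- length(usable)
    if (length(usable) >= min_sites) {
      out$fst[i] <- sum(comp$num[usable]) / sum(comp$den[usable])
      out$dxy[i] <- dxy_window(fq_pair$p[usable, 1], fq_pair$p[usable, 2],
                               wins$end[i] - wins$start[i])
    }
    sel <- which(pol_idx %in% idx)
    if (length(sel) >= min_sites) {
      out$d[i] <- d_stat_window(pol[sel, 1], pol[sel, 2], pol[sel, 3], pol[sel, 4])
      out$fd[i] <- fd_window(pol[sel, 1], pol[sel, 2], pol[sel, 3], pol[sel, 4])
    }
  }
  zf <- z_scan(out$fd, "two", p_cut)
  out$z_fd <- zf$z; out$p_fd <- zf$p; out$sig_fd <- zf$sig
  zs <- z_scan(out$fst, "upper", p_cut)
  out$z_fst <- zs$z; out$p_fst <- zs$p; out$sig_fst <- zs$sig
  out
}

#' Write a window-scan table as TSV (1-based inclusive coordinates)
#' @param scan data.frame from [scan_windows()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- scan
  out$start1 <- out$start + 1L
  cols <- c("contig", "start1", "end", "n_sites", "fst", "dxy", "d", "fd",
            "z_fd", "p_fd", "sig_fd", "z_fst", "p_fst", "sig_fst")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Permutation-derived genome-wide F_ST significance threshold
#'
#' For each replicate: draw `n_draw` samples from the pooled domestic groups,
#' pool them with all samples of the wild group, split the pool at random
#' into two equal pseudo-populations, compute windowed F_ST genome-wide and
#' record the maximum.  After `reps` replicates the largest recorded maximum
#' is returned as the threshold.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap popmap data.frame.
#' @param domestic_groups character vector of recipient group labels to pool.
#' @param wild_group donor group label.
#' @param n_draw number of domestic samples drawn per replicate (default 33,
#'   matching a donor panel of 33 samples).
#' @param reps number of permutation replicates (default 100).
#' @param size,step window size and step.
#' @param min_sites minimum usable sites per window.
#' @param seed integer seed.
#' @return the threshold (largest of the per-replicate maxima).
#' @export
fst_permutation_threshold <- function(panel, popmap, domestic_groups,
                                      wild_group, n_draw = 33L, reps = 100L,
                                      size = 50000L, step = 20000L,
                                      min_sites = 10L, seed = 1L) {
  dom <- popmap$sample[popmap$group %in% domestic_groups]
  wild <- popmap$sample[popmap$group == wild_group]
  if (length(dom) < n_draw) stop("fewer than n_draw domestic samples")
  if (length(wild) < 2) stop("wild group too small")
  wins <- iterate_windows(stats::setNames(panel$contigs$length,
                                          panel$contigs$contig), size, step)
  withr::with_seed(seed, {
    maxima <- vapply(seq_len(reps), function(rep) {
      pool <- c(sample(dom, n_draw), wild)
      half <- sample(pool, floor(length(pool) / 2))
      pm <- data.frame(sample = pool, breed = "perm",
                       group = ifelse(pool %in% half, "permA", "permB"),
                       stringsAsFactors = FALSE)
      comp <- fst_site_components_wc(panel, pm, "permA", "permB")
      vals <- vapply(seq_len(nrow(wins)), function(i) {
        idx <- sites_in_window(panel, wins$contig[i], wins$start[i], wins$end[i])
        usable <- idx[comp$usable[idx]]
        if (length(usable) < min_sites) return(NA_real_)
        sum(comp$num[usable]) / sum(comp$den[usable])
      }, numeric(1))
      max(vals, na.rm = TRUE)
    }, numeric(1))
    max(maxima)
  })
}
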