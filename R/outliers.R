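#' Frequency profiles of introgressed tract intervals across meta-populations
#'
#' For each candidate interval (by default the distinct merged donor tracts;
#' explicit intervals may be supplied), a recipient haplotype "carries" the
#' interval when its same-source ancestry covers at least `coverage_frac` of
#' it.  Frequencies are carriers/haplotypes per meta-population; the overall
#' frequency pools all recipient haplotypes; the SD and range are taken over
#' the per-meta-population frequencies with equal weight per meta-population.
#'
#' @param tracts inferred (filtered, merged) tract data.frame.
#' @param popmap popmap data.frame.
#' @param metapops character vector of recipient meta-population labels.
#' @param coverage_frac carrier coverage fraction (default 0.8).
#' @param candidates optional data.frame `contig`, `start`, `end`, `source`;
#'   default: unique donor tracts.
#' @param donor_sources sources counted as donors when deriving default
#'   candidates (default: all tract sources not named like a meta-population).
#' @return data.frame: one row per candidate with `id`, `contig`, `start`,
#'   `end`, `length`, `source`, one `freq_<metapop>` column per
#'   meta-population, `total_freq`, `sd`, `range`.
#' @export
tract_frequency <- function(tracts, popmap, metapops, coverage_frac = 0.8,
                            candidates = NULL, donor_sources = NULL) {
  hap_ids <- unlist(lapply(metapops, function(g) {
    s <- popmap$sample[popmap$group == g]
    if (!length(s)) stop("empty meta-population: ", g)
    paste0(rep(s, each = 2), c("_h1", "_h2"))
  }))
  hap_group <- rep(metapops, times = vapply(metapops, function(g)
    2L * sum(popmap$group == g), integer(1)))
  if (is.null(candidates)) {
    if (is.null(donor_sources))
      donor_sources <- setdiff(unique(tracts$source), metapops)
    cand <- unique(tracts[tracts$source %in% donor_sources,
                          c("contig", "start", "end", "source")])
  } else cand <- candidates
  if (!nrow(cand)) {
    return(data.frame(id = character(), contig = character(), start = numeric(),
                      end = numeric(), length = numeric(), source = character(),
                      total_freq = numeric(), sd = numeric(), range = numeric()))
  }
  cand$length <- cand$end - cand$start
  # coverage of each candidate by each haplotype's same-source tracts
  carries <- matrix(FALSE, nrow(cand), length(hap_ids),
                    dimnames = list(NULL, hap_ids))
  tr <- tracts[tracts$haplotype %in% hap_ids, , drop = FALSE]
  tr_by_hap <- split(tr, tr$haplotype)
  for (i in seq_len(nrow(cand))) {
    need <- coverage_frac * cand$length[i]
    for (h in names(tr_by_hap)) {
      tt <- tr_by_hap[[h]]
      tt <- tt[tt$contig == cand$contig[i] & tt$source == cand$source[i], ]
      if (!nrow(tt)) next
      cov <- sum(pmax(0, pmin(tt$end, cand$end[i]) - pmax(tt$start, cand$start[i])))
      carries[i, h] <- cov >= need
    }
  }
  freq <- sapply(metapops, function(g)
    rowMeans(carries[, hap_group == g, drop = FALSE]))
  freq <- matrix(freq, nrow = nrow(cand),
                 dimnames = list(NULL, paste0("freq_", metapops)))
  out <- data.frame(id = sprintf("tract_%04d", seq_len(nrow(cand))),
                    cand, stringsAsFactors = FALSE)
  out <- cbind(out, freq)
  out$total_freq <- rowMeans(carries)
  out$sd <- apply(freq, 1, stats::sd)
  out$range <- apply(freq, 1, function(x) max(x) - min(x))
  out
}

#' Select outlier introgressed tracts
#'
#' Keeps profiles with `length >= min_len`, `total_freq >= min_total_freq`
#' and `sd > min_sd` — long tracts at appreciable overall frequency whose
#' frequency varies strongly across meta-populations, the signature of
#' population-specific (potentially adaptive) introgression.
#'
#' @param profiles data.frame from [tract_frequency()].
#' @param min_len minimum length in bp (default 100000).
#' @param min_total_freq minimum pooled frequency (default 0.05).
#' @param min_sd minimum (exclusive) SD across meta-populations (default 0.1).
#' @return the selected rows of `profiles`.
#' @export
select_outlier_tracts <- function(profiles, min_len = 100000,
                                  min_total_freq = 0.05, min_sd = 0.1) {
  keep <- profiles$length >= min_len &
    profiles$total_freq >= min_total_freq &
    profiles$sd > min_sd
  profiles[keep, , drop = FALSE]
}

#' Build highly differentiated regions from an F_ST window scan
#'
#' Significant windows (`p_fst < p_cut`, upper tail) are merged into
#' non-overlapping regions, joining windows separated by at most `join_gap`
#' bp.
#'
#' @param window_stats data.frame from [scan_windows()] (needs `contig`,
#'   `start`, `end`, `p_fst`).
#' @param p_cut P-value cutoff (default 0.001).
#' @param join_gap maximum gap between joined windows in bp (default 50000).
#' @return data.frame with `contig`, `start`, `end`, `n_windows`, `min_p`.
#' @export
high_fst_regions <- function(window_stats, p_cut = 0.001, join_gap = 50000) {
  sig <- window_stats[!is.na(window_stats$p_fst) & window_stats$p_fst < p_cut, ]
  if (!nrow(sig))
    return(data.frame(contig = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), min_p = numeric()))
  out <- list()
  for (ctg in unique(sig$contig)) {
    df <- sig[sig$contig == ctg, ]
    df <- df[order(df$start), ]
    cs <- df$start[1]; ce <- df$end[1]; n <- 1L; mp <- df$p_fst[1]
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] - ce <= join_gap) {
        ce <- max(ce, df$end[i]); n <- n + 1L; mp <- min(mp, df$p_fst[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(contig = ctg, start = cs, end = ce,
                                              n_windows = n, min_p = mp)
        cs <- df$start[i]; ce <- df$end[i]; n <- 1L; mp <- df$p_fst[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(contig = ctg, start = cs, end = ce,
                                          n_windows = n, min_p = mp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate outlier tracts with overlapping high-F_ST regions
#'
#' @param outliers data.frame of selected profiles (needs `contig`, `start`,
#'   `end`).
#' @param regions data.frame from [high_fst_regions()].
#' @param min_overlap minimum overlap in bp (default 1).
#' @return `outliers` with added columns `n_regions` and `region_ids`
#'   (comma-separated indices into `regions`, "" if none).
#' @export
overlap_regions <- function(outliers, regions, min_overlap = 1) {
  n_regions <- integer(nrow(outliers))
  region_ids <- character(nrow(outliers))
  for (i in seq_len(nrow(outliers))) {
    hit <- which(regions$contig == outliers$contig[i] &
                 pmin(regions$end, outliers$end[i]) -
                 pmax(regions$start, outliers$start[i]) >= min_overlap)
    n_regions[i] <- length(hit)
    region_ids[i] <- paste(hit, collapse = ",")
  }
  outliers$n_regions <- n_regions
  outliers$region_ids <- region_ids
  outliers
}
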