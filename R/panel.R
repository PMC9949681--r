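#' Construct a phased haplotype panel
#'
#' The central container of the package: a matrix of phased biallelic alleles
#' over genomic sites.  Rows are sites, columns are haplotypes; entries are 0
#' (reference/ancestral-candidate allele), 1 (alternate) or `NA` (missing).
#' Haplotype ids are `<sample>_h1` / `<sample>_h2`; every sample contributes
#' exactly two haplotypes.  Coordinates are 0-based half-open throughout the
#' package; they are converted to 1-based only when reading/writing VCF.
#'
#' @param contigs data.frame with columns `contig` (character) and
#'   `length` (bp).
#' @param sites data.frame with columns `contig` and `pos` (0-based bp),
#'   strictly increasing within each contig.
#' @param alleles integer matrix, `nrow(sites)` x `2 * n_samples`, values in
#'   \{0, 1, NA\}.
#' @param sample_ids character vector of sample names.
#' @return An object of class `haplotype_panel` with elements `contigs`,
#'   `sites`, `alleles`, `sample_ids`, `hap_ids`, and `hap_sample` (the sample
#'   each haplotype belongs to).
#' @export
haplotype_panel <- function(contigs, sites, alleles, sample_ids) {
  stopifnot(is.data.frame(contigs), all(c("contig", "length") %in% names(contigs)))
  stopifnot(is.data.frame(sites), all(c("contig", "pos") %in% names(sites)))
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != nrow(sites))
    stop("allele matrix has ", nrow(alleles), " rows but ", nrow(sites), " sites")
  if (ncol(alleles) != 2L * length(sample_ids))
    stop("allele matrix has ", ncol(alleles), " columns; expected 2 haplotypes for each of ",
         length(sample_ids), " samples")
  bad <- !(alleles %in% c(0L, 1L, NA))
  if (any(bad)) stop("allele matrix must contain only 0, 1 or NA")
  for (ctg in unique(sites$contig)) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0)) stop("site positions not strictly increasing on contig ", ctg)
    len <- contigs$length[match(ctg, contigs$contig)]
    if (is.na(len)) stop("sites reference unknown contig ", ctg)
    if (any(p < 0) || any(p >= len)) stop("site positions outside contig bounds on ", ctg)
  }
  hap_ids <- as.vector(t(outer(sample_ids, c("_h1", "_h2"), paste0)))
  colnames(alleles) <- hap_ids
  structure(
    list(contigs = contigs, sites = sites, alleles = alleles,
         sample_ids = sample_ids, hap_ids = hap_ids,
         hap_sample = rep(sample_ids, each = 2L)),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$sites), "sites,",
      length(x$hap_ids), "haplotypes (", length(x$sample_ids), "samples ) on",
      nrow(x$contigs), "contig(s)\n")
  invisible(x)
}

#' Number of haplotypes in a panel
#' @param panel a `haplotype_panel`.
#' @return integer count of haplotypes (2 per sample).
#' @export
n_haplotypes <- function(panel) length(panel$hap_ids)

#' Haplotype ids belonging to a set of population groups
#'
#' @param panel a `haplotype_panel`.
#' @param popmap a popmap data.frame (see [read_popmap()]).
#' @param groups character vector of group labels.
#' @return character vector of haplotype ids.
#' @export
group_haplotypes <- function(panel, popmap, groups) {
  samples <- popmap$sample[popmap$group %in% groups]
  panel$hap_ids[panel$hap_sample %in% samples]
}

#' Enumerate sliding windows over contigs
#'
#' Windows start at 0 and advance by `step`; the terminal windows are clipped
#' at the contig end and flagged.  The default 50-kb window with 20-kb step is
#' the grid used for all window statistics in the pipeline.
#'
#' @param contig_lengths named numeric vector (names = contig ids) or a
#'   data.frame with columns `contig`, `length`.
#' @param size window size in bp (default 50000).
#' @param step step in bp (default 20000); must satisfy `size >= step > 0`.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and logical `clipped`.
#' @export
iterate_windows <- function(contig_lengths, size = 50000L, step = 20000L) {
  if (is.data.frame(contig_lengths)) {
    lens <- stats::setNames(contig_lengths$length, contig_lengths$contig)
  } else lens <- contig_lengths
  if (!(size >= step && step > 0)) stop("require size >= step > 0")
  out <- lapply(names(lens), function(ctg) {
    len <- lens[[ctg]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + size, len)
    data.frame(contig = ctg, start = starts, end = ends,
               clipped = (ends - starts) < size, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Validate a popmap against a panel
#'
#' @param panel a `haplotype_panel`.
#' @param popmap popmap data.frame with columns `sample`, `breed`, `group`.
#' @return invisibly `TRUE`; errors naming any unmapped sample.
#' @export
validate_popmap <- function(panel, popmap) {
  missing <- setdiff(panel$sample_ids, popmap$sample)
  if (length(missing))
    stop("popmap is missing panel sample(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Per-site derived/alternate allele frequency and allele counts for groups
#'
#' Missing alleles are excluded from both numerator and denominator.
#'
#' @param panel a `haplotype_panel`.
#' @param popmap popmap data.frame.
#' @param groups character vector of group labels.
#' @param site_idx optional integer vector of site rows (default all).
#' @return list with matrices `p` (frequency) and `n` (non-missing allele
#'   count), sites x groups.
#' @export
group_freqs <- function(panel, popmap, groups, site_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(panel$sites))
  p <- matrix(NA_real_, length(site_idx), length(groups),
              dimnames = list(NULL, groups))
  n <- matrix(0L, length(site_idx), length(groups), dimnames = list(NULL, groups))
  for (g in groups) {
    haps <- group_haplotypes(panel, popmap, g)
    if (!length(haps)) stop("group has no haplotypes in panel: ", g)
    sub <- panel$alleles[site_idx, haps, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    p[, g] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / nn, NA_real_)
    n[, g] <- nn
  }
  list(p = p, n = n)
}

#' Indices of panel sites falling in a window
#' @param panel a `haplotype_panel`.
#' @param contig contig id.
#' @param start,end 0-based half-open interval.
#' @return integer vector of site row indices.
#' @export
sites_in_window <- function(panel, contig, start, end) {
  which(panel$sites$contig == contig &
        panel$sites$pos >= start & panel$sites$pos < end)
}
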