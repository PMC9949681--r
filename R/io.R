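#' Read a phased VCF into a haplotype panel
#'
#' Parses the GT field only.  Multiallelic records are dropped (counted and
#' reported with a message).  Unphased genotypes are an error unless
#' `allow_unphased = TRUE`, in which case the offending records are dropped.
#' Missing calls (`.|.` or `./.`) become `NA` alleles.  Contig lengths are
#' taken from `##contig` header lines when present, otherwise from the largest
#' observed position per contig.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param allow_unphased drop unphased records instead of erroring.
#' @return a [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi))
    message("read_phased_vcf: dropped ", sum(multi), " non-biallelic record(s)")
  gt <- v@gt[, -1, drop = FALSE]
  samples <- colnames(gt)
  # strip any extra FORMAT fields
  gt <- sub(":.*$", "", gt)
  keep <- !multi
  unphased <- apply(gt, 1, function(r) any(grepl("[0-9]/[0-9]", r)))
  if (any(unphased & keep)) {
    if (!allow_unphased)
      stop("VCF contains ", sum(unphased & keep),
           " record(s) with unphased genotypes; use allow_unphased = TRUE to drop them")
    message("read_phased_vcf: dropped ", sum(unphased & keep), " unphased record(s)")
    keep <- keep & !unphased
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  n_site <- nrow(gt)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_int <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out  # "." -> NA
  }
  alleles <- matrix(NA_integer_, n_site, 2L * length(samples))
  alleles[, seq(1, ncol(alleles), by = 2)] <- to_int(a1)
  alleles[, seq(2, ncol(alleles), by = 2)] <- to_int(a2)
  pos <- as.integer(fix[, "POS"]) - 1L  # to 0-based
  ctg <- fix[, "CHROM"]
  ord <- order(match(ctg, unique(ctg)), pos)
  sites <- data.frame(contig = ctg[ord], pos = pos[ord], stringsAsFactors = FALSE)
  alleles <- alleles[ord, , drop = FALSE]
  # contig lengths from header if available
  meta <- v@meta
  clines <- grep("^##contig=", meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", clines)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", clines)))
  contigs <- data.frame(contig = unique(sites$contig), stringsAsFactors = FALSE)
  contigs$length <- ifelse(contigs$contig %in% ids,
                           lens[match(contigs$contig, ids)], NA_real_)
  mx <- tapply(sites$pos, sites$contig, max)
  contigs$length[is.na(contigs$length)] <-
    mx[contigs$contig[is.na(contigs$length)]] + 1
  haplotype_panel(contigs, sites, alleles, samples)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal deterministic VCF 4.2 (GT only, `0|1`-style genotypes,
#' `##contig` header lines carrying contig lengths, no date stamp so that
#' identical panels yield byte-identical files).  Internal 0-based positions
#' are converted to 1-based VCF coordinates.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_phased_vcf <- function(panel, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ovintro",
           sprintf("##contig=<ID=%s,length=%d>",
                   panel$contigs$contig, as.integer(panel$contigs$length)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  al <- panel$alleles
  al_chr <- matrix(as.character(al), nrow(al), ncol(al))
  al_chr[is.na(al_chr)] <- "."
  i1 <- seq(1, ncol(al), by = 2)
  gt <- matrix(paste0(al_chr[, i1, drop = FALSE], "|", al_chr[, i1 + 1, drop = FALSE]),
               nrow(al), length(i1))
  body <- paste(panel$sites$contig, panel$sites$pos + 1L,
                paste0("s", seq_len(nrow(al))), "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-breed-to-group popmap
#'
#' Tab-separated with three columns: sample, breed, group.  Groups are the
#' analysis units: donor species labels, the outgroup, the non-introgressed
#' reference group and the recipient meta-populations.
#'
#' @param path TSV path (header optional; detected from the first line).
#' @return data.frame with columns `sample`, `breed`, `group`.
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- identical(tolower(strsplit(first, "\t")[[1]][1]), "sample")
  df <- if (has_header)
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("sample", "breed", "group"))
  names(df) <- c("sample", "breed", "group")
  if (any(!stats::complete.cases(df)))
    stop("malformed popmap line(s): ",
         paste(which(!stats::complete.cases(df)), collapse = ", "))
  df
}

#' Write a popmap TSV
#' @param popmap data.frame with `sample`, `breed`, `group`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap[, c("sample", "breed", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ancestry tracts from BED
#'
#' BED3+ with columns: contig, start, end, haplotype, source (0-based
#' half-open, as written by [write_tracts_bed()]).
#'
#' @param path BED path.
#' @return data.frame with columns `haplotype`, `contig`, `start`, `end`,
#'   `source`, `length`.
#' @export
read_tracts_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("tract BED needs 5 columns: contig start end haplotype source")
  names(df)[1:5] <- c("contig", "start", "end", "haplotype", "source")
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)
    stop("malformed BED interval at line(s): ", paste(bad, collapse = ", "))
  }
  data.frame(haplotype = df$haplotype, contig = df$contig,
             start = df$start, end = df$end, source = df$source,
             length = df$end - df$start, stringsAsFactors = FALSE)
}

#' Write ancestry tracts to BED
#'
#' Records are sorted (contig, start, haplotype) and exact duplicates dropped,
#' so the file round-trips losslessly through [read_tracts_bed()].
#'
#' @param tracts tract data.frame (see [read_tracts_bed()] for columns).
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_tracts_bed <- function(tracts, path) {
  df <- unique(tracts[, c("contig", "start", "end", "haplotype", "source")])
  df <- df[order(df$contig, df$start, df$haplotype), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-interval recombination map
#'
#' TSV with columns contig, start, end, rate (per bp per generation; 0-based
#' half-open intervals).  [lookup_recomb_rate()] queries it.
#'
#' @param path TSV path.
#' @return data.frame with columns `contig`, `start`, `end`, `rate`.
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "rate")
  if (!all(need %in% names(df))) stop("recomb map needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$rate)) || any(df$rate < 0)) {
    stop("malformed recomb map rate at line(s): ",
         paste(which(!is.finite(df$rate) | df$rate < 0), collapse = ", "))
  }
  df
}

#' Look up the local recombination rate at a position
#'
#' Returns the rate of the covering interval, or `default` if the position
#' falls in a gap of the map (or the map is `NULL`).
#'
#' @param map recombination map from [read_recomb_map()], or `NULL`.
#' @param contig contig id.
#' @param pos 0-based position (vectorized).
#' @param default genome-wide default rate (per bp per generation).
#' @return numeric vector of rates.
#' @export
lookup_recomb_rate <- function(map, contig, pos, default = 1e-8) {
  if (is.null(map)) return(rep(default, length(pos)))
  out <- rep(default, length(pos))
  sub <- map[map$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    hit <- pos >= sub$start[i] & pos < sub$end[i]
    out[hit] <- sub$rate[i]
  }
  out
}
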