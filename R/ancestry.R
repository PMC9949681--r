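#' Minimal-cost haplotype copying path (dynamic programming)
#'
#' Models an admixed haplotype as a mosaic of reference-panel template
#' haplotypes: the returned path minimizes
#' `n_mismatches + lambda * n_switches` over all assignments of one template
#' per site.  Ties are broken in favor of fewer switches, then the lowest
#' template index.  Complexity O(n_sites x n_templates).  Missing alleles (in
#' target or template) incur no mismatch.
#'
#' @param target integer vector of target alleles (0/1/NA).
#' @param templates matrix n_sites x n_templates of reference alleles.
#' @param sources character vector: source population of each template.
#' @param lambda switch penalty in mismatch-equivalents (default 5).
#' @return list with `path` (template index per site), `source` (source
#'   population per site), `n_switches`, `n_mismatches`, `cost`.
#' @export
copy_path_dp <- function(target, templates, sources, lambda = 5) {
  templates <- as.matrix(templates)
  n <- length(target); Tn <- ncol(templates)
  if (Tn == 0) stop("empty reference panel")
  stopifnot(nrow(templates) == n, length(sources) == Tn)
  mism <- templates != target
  mism[is.na(mism)] <- FALSE
  mism <- matrix(as.numeric(mism), n, Tn)
  C <- mism[1, ]
  S <- rep(0L, Tn)
  ptr <- matrix(0L, n, Tn)  # 0 = stay; >0 = switched from that template
  for (i in seq_len(n)[-1]) {
    best <- order(C, S, seq_len(Tn))[1]
    sw_cost <- C[best] + lambda
    sw_S <- S[best] + 1L
    take_switch <- (sw_cost < C) | (sw_cost == C & sw_S < S)
    take_switch[best] <- FALSE  # switching to itself is never beneficial
    newC <- ifelse(take_switch, sw_cost, C) + mism[i, ]
    newS <- ifelse(take_switch, sw_S, S)
    ptr[i, ] <- ifelse(take_switch, best, 0L)
    C <- newC; S <- newS
  }
  end <- order(C, S, seq_len(Tn))[1]
  path <- integer(n)
  path[n] <- end
  for (i in seq(n, 2)) {
    path[i - 1] <- if (ptr[i, path[i]] > 0) ptr[i, path[i]] else path[i]
  }
  n_sw <- sum(diff(path) != 0)
  n_mm <- sum(mism[cbind(seq_len(n), path)])
  list(path = path, source = sources[path], n_switches = n_sw,
       n_mismatches = n_mm, cost = n_mm + lambda * n_sw)
}

site_runs_to_tracts <- function(src, pos, contig, contig_len, haplotype) {
  runs <- rle(src)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  n <- length(runs$values)
  # boundary between runs: midpoint between last site of one run and first of next
  bounds <- if (n > 1)
    floor((pos[ends_idx[-n]] + pos[starts_idx[-1]]) / 2) + 1 else numeric(0)
  starts <- c(0, bounds)
  ends <- c(bounds, contig_len)
  data.frame(haplotype = haplotype, contig = contig, start = starts,
             end = ends, source = runs$values, length = ends - starts,
             stringsAsFactors = FALSE)
}

#' Infer local-ancestry tracts for all haplotypes of a target group
#'
#' Runs [copy_path_dp()] for every target haplotype against the pooled
#' reference haplotypes of the source groups (the non-introgressed recipient
#' reference group must be among them so that "no donor" is expressible),
#' converts per-site source runs into tracts with boundaries at the midpoint
#' between flanking sites, and merges adjacent same-source runs.  Optional
#' bagging repeats the DP on random template subsets (fraction `bag_frac`)
#' and takes a per-site majority vote, ties resolved to `recipient_group`.
#'
#' @param panel a [haplotype_panel()].
#' @param popmap popmap data.frame.
#' @param target_group group label of the admixed recipients.
#' @param reference_groups source group labels (disjoint from the target).
#' @param lambda switch penalty (default 5; see the methods vignette for the
#'   sensitivity analysis behind this choice).
#' @param bagging_reps 0 or 1 for plain DP (default), else number of bagging
#'   replicates (20 is a reasonable choice).
#' @param bag_frac template subsample fraction per replicate (default 0.8).
#' @param recipient_group label whose ancestry wins vote ties (default the
#'   first reference group).
#' @param seed integer seed (used only when bagging).
#' @return tract data.frame (`haplotype`, `contig`, `start`, `end`, `source`,
#'   `length`); per haplotype and contig the tracts partition `[0, length)`.
#' @export
infer_tracts <- function(panel, popmap, target_group, reference_groups,
                         lambda = 5, bagging_reps = 0L, bag_frac = 0.8,
                         recipient_group = reference_groups[1], seed = 1L) {
  if (target_group %in% reference_groups)
    stop("target group must not be among the reference groups")
  ref_haps <- unlist(lapply(reference_groups, function(g)
    group_haplotypes(panel, popmap, g)))
  if (!length(ref_haps)) stop("empty reference panel")
  ref_src <- rep(reference_groups,
                 vapply(reference_groups, function(g)
                   length(group_haplotypes(panel, popmap, g)), integer(1)))
  tgt_haps <- group_haplotypes(panel, popmap, target_group)
  out <- list()
  for (ci in seq_len(nrow(panel$contigs))) {
    ctg <- panel$contigs$contig[ci]
    len <- panel$contigs$length[ci]
    idx <- which(panel$sites$contig == ctg)
    pos <- panel$sites$pos[idx]
    tmpl <- panel$alleles[idx, ref_haps, drop = FALSE]
    for (h in tgt_haps) {
      tgt <- panel$alleles[idx, h]
      if (bagging_reps > 1L) {
        votes <- withr::with_seed(seed + match(h, tgt_haps), {
          vv <- replicate(bagging_reps, {
            sub <- sort(sample(ncol(tmpl), max(1L, ceiling(bag_frac * ncol(tmpl)))))
            copy_path_dp(tgt, tmpl[, sub, drop = FALSE], ref_src[sub], lambda)$source
          })
          matrix(vv, nrow = length(tgt))
        })
        src <- apply(votes, 1, function(v) {
          tab <- table(v)
          top <- names(tab)[tab == max(tab)]
          if (length(top) > 1 && recipient_group %in% top) recipient_group
          else top[1]
        })
      } else {
        src <- copy_path_dp(tgt, tmpl, ref_src, lambda)$source
      }
      out[[length(out) + 1L]] <- site_runs_to_tracts(src, pos, ctg, len, h)
    }
  }
  do.call(rbind, out)
}

#' Merge same-haplotype same-source tracts
#'
#' Tracts that overlap or lie within `max_gap` bp of each other and share
#' haplotype, contig and source are merged; lengths are recomputed.
#'
#' @param tracts tract data.frame.
#' @param max_gap maximum gap to bridge (default 0 = touching or overlapping).
#' @return merged tract data.frame, sorted.
#' @export
merge_tracts <- function(tracts, max_gap = 0) {
  if (!nrow(tracts)) return(tracts)
  key <- paste(tracts$haplotype, tracts$contig, tracts$source, sep = "\r")
  out <- lapply(split(tracts, key), function(df) {
    df <- df[order(df$start), ]
    ms <- df$start[1]; me <- df$end[1]
    starts <- ends <- numeric(0)
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] <= me + max_gap) {
        me <- max(me, df$end[i])
      } else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- df$start[i]; me <- df$end[i]
      }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    data.frame(haplotype = df$haplotype[1], contig = df$contig[1],
               start = starts, end = ends, source = df$source[1],
               length = ends - starts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$haplotype, out$contig, out$start), ]
}

#' Per-source ancestry fractions of inferred tracts
#' @param tracts tract data.frame (partitioning tracts from [infer_tracts()]).
#' @return named numeric vector: fraction of total tract bp per source.
#' @export
ancestry_fractions <- function(tracts) {
  tot <- sum(tracts$length)
  vapply(split(tracts$length, tracts$source), sum, numeric(1)) / tot
}

#' Base-pair precision and recall of inferred tracts against ground truth
#'
#' Both sets are restricted to the given source and to tracts of at least
#' `min_len` bp; overlap is computed per haplotype and contig.
#'
#' @param pred inferred tract data.frame.
#' @param truth ground-truth tract data.frame.
#' @param source donor source label to evaluate.
#' @param min_len minimum tract length (bp) on both sides (default 0).
#' @return list with `precision`, `recall`, `overlap_bp`, `pred_bp`,
#'   `truth_bp`.
#' @export
tract_accuracy <- function(pred, truth, source, min_len = 0) {
  p <- pred[pred$source == source & pred$length >= min_len, ]
  t <- truth[truth$source == source & truth$length >= min_len, ]
  ov <- 0
  for (i in seq_len(nrow(p))) {
    tt <- t[t$haplotype == p$haplotype[i] & t$contig == p$contig[i], ]
    if (!nrow(tt)) next
    ov <- ov + sum(pmax(0, pmin(tt$end, p$end[i]) - pmax(tt$start, p$start[i])))
  }
  list(precision = if (nrow(p)) ov / sum(p$length) else NA_real_,
       recall = if (nrow(t)) ov / sum(t$length) else NA_real_,
       overlap_bp = ov, pred_bp = sum(p$length), truth_bp = sum(t$length))
}
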