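#' Extract phased haplotypes of a candidate region
#'
#' Pulls the phased alleles of all haplotypes in `[start, end)` and removes
#' sites with minor allele frequency at or below `maf_min` (MAF computed over
#' all non-missing alleles in the region).
#'
#' @param panel a [haplotype_panel()].
#' @param contig contig id.
#' @param start,end region, 0-based half-open.
#' @param maf_min sites with MAF <= this value are removed (default 0.05).
#' @return object of class `region_haplotypes`: list with `contig`, `start`,
#'   `end`, `positions`, `haps` (matrix haplotypes x sites), `hap_ids`,
#'   `hap_sample`.
#' @export
extract_region <- function(panel, contig, start, end, maf_min = 0.05) {
  idx <- sites_in_window(panel, contig, start, end)
  if (!length(idx)) stop("no sites in region")
  sub <- panel$alleles[idx, , drop = FALSE]
  p <- rowMeans(sub, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_min
  if (!any(keep)) stop("region monomorphic (or all sites below MAF cutoff)")
  structure(list(contig = contig, start = start, end = end,
                 positions = panel$sites$pos[idx][keep],
                 haps = t(sub[keep, , drop = FALSE]),
                 hap_ids = panel$hap_ids, hap_sample = panel$hap_sample),
            class = "region_haplotypes")
}

#' @export
print.region_haplotypes <- function(x, ...) {
  cat("region_haplotypes:", x$contig, paste0("[", x$start, ",", x$end, ")"),
      "-", ncol(x$haps), "sites x", nrow(x$haps), "haplotypes\n")
  invisible(x)
}

hamming <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  sum(a[ok] != b[ok])
}

#' Screen out recombinant haplotypes in a region
#'
#' Consensus seeds are the `k_major` most frequent distinct haplotypes.  A
#' haplotype within `max_diff_frac * n_sites` mismatches of some consensus is
#' kept outright.  Otherwise it is aligned to every single consensus and to
#' every 2-segment chimera of two consensus strings; it is flagged as a
#' recombinant when the best chimera beats the best single consensus by at
#' least `margin` mismatches (a haplotype that is half one major haplotype
#' and half another).
#'
#' @param rh a `region_haplotypes` from [extract_region()].
#' @param k_major number of consensus seeds (default 3; reduced with a
#'   warning if fewer distinct haplotypes exist).
#' @param max_diff_frac keep-outright distance fraction (default 0.1).
#' @param margin chimera advantage in mismatches (default 5).
#' @return list with `kept` and `flagged` (character vectors of haplotype
#'   ids) and `consensus` (matrix of the seed haplotypes).
#' @export
screen_recombinants <- function(rh, k_major = 3L, max_diff_frac = 0.1,
                                margin = 5L) {
  strs <- apply(rh$haps, 1, paste, collapse = "")
  tab <- sort(table(strs), decreasing = TRUE)
  if (length(tab) < k_major) {
    warning("only ", length(tab), " distinct haplotypes; reducing k_major")
    k_major <- length(tab)
  }
  cons <- do.call(rbind, lapply(names(tab)[seq_len(k_major)], function(s)
    as.integer(strsplit(s, "")[[1]])))
  n_sites <- ncol(rh$haps)
  flagged <- character(0)
  for (i in seq_len(nrow(rh$haps))) {
    h <- rh$haps[i, ]
    dists <- apply(cons, 1, hamming, b = h)
    best_single <- min(dists)
    if (best_single <= max_diff_frac * n_sites) next
    # best 2-segment chimera over all ordered consensus pairs via cumulative
    # mismatch counts
    mm <- t(apply(cons, 1, function(cs) as.integer(cs != h)))
    best_chim <- best_single
    for (a in seq_len(k_major)) for (b in seq_len(k_major)) {
      if (a == b) next
      left <- cumsum(mm[a, ])                      # mismatches in h[1..k] vs a
      right <- rev(cumsum(rev(mm[b, ])))           # mismatches in h[k..n] vs b
      sc <- min(left[-n_sites] + right[-1])        # breakpoint between k,k+1
      best_chim <- min(best_chim, sc)
    }
    if (best_single - best_chim >= margin)
      flagged <- c(flagged, rh$hap_ids[i])
  }
  list(kept = setdiff(rh$hap_ids, flagged), flagged = flagged,
       consensus = cons)
}

#' Cluster region haplotypes into haplogroups
#'
#' Single-linkage clustering on pairwise Hamming distance (pairwise-complete
#' over missing sites), cut at `max_diff_frac * n_sites`; groups are ordered
#' by size and labelled `hap-1`, `hap-2`, ...  The consensus of a group is
#' the per-site majority allele.
#'
#' @param rh a `region_haplotypes`.
#' @param max_diff_frac within-group distance fraction (default 0.05).
#' @param hap_ids optional subset of haplotype ids to cluster (e.g. the
#'   `kept` set of [screen_recombinants()]).
#' @return data.frame with columns `haplotype`, `group` (label), plus
#'   attribute `consensus` (list of consensus vectors by group).
#' @export
cluster_haplogroups <- function(rh, max_diff_frac = 0.05, hap_ids = NULL) {
  sel <- if (is.null(hap_ids)) seq_len(nrow(rh$haps)) else
    match(hap_ids, rh$hap_ids)
  H <- rh$haps[sel, , drop = FALSE]
  ids <- rh$hap_ids[sel]
  n <- nrow(H)
  cutoff <- max_diff_frac * ncol(H)
  if (n == 1) {
    memb <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- hamming(H[i, ], H[j, ])
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    memb <- stats::cutree(hc, h = cutoff)
  }
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  lab <- paste0("hap-", relabel[as.character(memb)])
  out <- data.frame(haplotype = ids, group = lab, stringsAsFactors = FALSE)
  cons <- lapply(split(seq_len(n), lab), function(ii) {
    as.integer(round(colMeans(H[ii, , drop = FALSE], na.rm = TRUE)))
  })
  attr(out, "consensus") <- cons
  out
}

#' Per-breed haplogroup frequency table
#'
#' Counts carriers per breed and overall; frequencies are reported both as
#' exact fractions (`carriers/haplotypes`) and rounded (round-half-even) to 3
#' decimals, so either printing convention is recoverable.
#'
#' @param groups data.frame from [cluster_haplogroups()] (columns `haplotype`,
#'   `group`).
#' @param popmap popmap data.frame (haplotype ids are `<sample>_h1/2`).
#' @return data.frame with `group`, `breed` (or `"ALL"`), `carriers`,
#'   `haplotypes`, `fraction` (string), `frequency` (3 decimals).
#' @export
haplogroup_frequencies <- function(groups, popmap) {
  samp <- sub("_h[12]$", "", groups$haplotype)
  breed <- popmap$breed[match(samp, popmap$sample)]
  if (any(is.na(breed)))
    stop("popmap does not cover sample(s): ",
         paste(unique(samp[is.na(breed)]), collapse = ", "))
  out <- list()
  add_rows <- function(label, mask) {
    tot <- sum(mask)
    for (g in sort(unique(groups$group))) {
      k <- sum(mask & groups$group == g)
      out[[length(out) + 1L]] <<- data.frame(
        group = g, breed = label, carriers = k, haplotypes = tot,
        fraction = sprintf("%d/%d", k, tot),
        frequency = round(k / tot, 3), stringsAsFactors = FALSE)
    }
  }
  add_rows("ALL", rep(TRUE, nrow(groups)))
  for (b in sort(unique(breed))) add_rows(b, breed == b)
  do.call(rbind, out)
}

#' Haplotype network from pairwise differences
#'
#' Collapses identical haplotypes into nodes with multiplicities, computes
#' the pairwise Hamming distance matrix (pairwise-complete over missing
#' sites) and a minimum spanning tree (Prim's algorithm with a deterministic
#' tie-break: smallest weight, then smallest node index in input order).
#' Non-MST edges are flagged `alternative` when their weight does not exceed
#' the largest weight on the MST path between their endpoints (they could
#' substitute for an MST edge without increasing the total weight).
#'
#' @param rh a `region_haplotypes`, or a plain 0/1 matrix (haplotypes x
#'   sites) with rownames as ids.
#' @param alt_edges also report alternative edges (default TRUE).
#' @return object of class `haplo_network`: list with `nodes` (data.frame
#'   `node`, `multiplicity`, `members`), `edges` (data.frame `from`, `to`,
#'   `weight`, `in_mst`, `alternative`) and `dist` (matrix).
#' @export
build_network <- function(rh, alt_edges = TRUE) {
  H <- if (inherits(rh, "region_haplotypes")) rh$haps else as.matrix(rh)
  ids <- if (inherits(rh, "region_haplotypes")) rh$hap_ids else
    (if (is.null(rownames(H))) paste0("h", seq_len(nrow(H))) else rownames(H))
  strs <- apply(H, 1, paste, collapse = "")
  uniq <- !duplicated(strs)
  U <- H[uniq, , drop = FALSE]
  ustr <- strs[uniq]
  if (nrow(U) < 2) stop("need at least 2 distinct haplotypes")
  nodes <- data.frame(node = paste0("N", seq_len(nrow(U))),
                      multiplicity = as.integer(table(strs)[ustr]),
                      members = vapply(ustr, function(s)
                        paste(ids[strs == s], collapse = ","), character(1)),
                      stringsAsFactors = FALSE)
  n <- nrow(U)
  d <- matrix(0, n, n, dimnames = list(nodes$node, nodes$node))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- hamming(U[i, ], U[j, ])
  }
  # Prim's MST, deterministic: grow from node 1; at each step add the
  # minimum-weight crossing edge, ties by smallest inside then outside index
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  mst <- matrix(0L, 0, 2)
  while (any(!in_tree)) {
    best <- NULL
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      cand <- c(d[i, j], i, j)
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] && (cand[2] < best[2] ||
           (cand[2] == best[2] && cand[3] < best[3]))))
        best <- cand
    }
    mst <- rbind(mst, best[2:3])
    in_tree[best[3]] <- TRUE
  }
  in_mst <- matrix(FALSE, n, n)
  in_mst[mst] <- TRUE
  in_mst <- in_mst | t(in_mst)
  # adjacency for MST path maxima
  path_max <- function(a, b) {
    # BFS from a to b over MST, tracking max edge weight
    seen <- rep(FALSE, n); seen[a] <- TRUE
    front <- list(list(node = a, mx = 0))
    while (length(front)) {
      nxt <- list()
      for (f in front) {
        for (k in which(in_mst[f$node, ] & !seen)) {
          mx <- max(f$mx, d[f$node, k])
          if (k == b) return(mx)
          seen[k] <- TRUE
          nxt[[length(nxt) + 1L]] <- list(node = k, mx = mx)
        }
      }
      front <- nxt
    }
    Inf
  }
  edges <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    is_mst <- in_mst[i, j]
    alt <- FALSE
    if (!is_mst && alt_edges) alt <- d[i, j] <= path_max(i, j)
    if (is_mst || alt)
      edges[[length(edges) + 1L]] <- data.frame(
        from = nodes$node[i], to = nodes$node[j], weight = d[i, j],
        in_mst = is_mst, alternative = alt, stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = do.call(rbind, edges), dist = d),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", nrow(x$nodes), "nodes,",
      sum(x$edges$in_mst), "MST edges (total weight",
      sum(x$edges$weight[x$edges$in_mst]), "),",
      sum(x$edges$alternative), "alternative edges\n")
  invisible(x)
}
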