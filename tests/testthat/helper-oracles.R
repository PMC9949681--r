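# Independent brute-force oracles used to validate the optimized
# implementations.  Each is a literal transcription of the defining
# computation, kept free of any package internals.

# exhaustive minimum over all template-per-site assignments
oracle_copy_path_cost <- function(target, templates, lambda) {
  n <- length(target); Tn <- ncol(templates)
  mism <- templates != target
  mism[is.na(mism)] <- FALSE
  paths <- as.matrix(expand.grid(rep(list(seq_len(Tn)), n)))
  cost <- numeric(nrow(paths))
  for (i in seq_len(n)) cost <- cost + mism[i, paths[, i]]
  if (n > 1)
    cost <- cost + lambda *
      rowSums(paths[, -1, drop = FALSE] != paths[, -n, drop = FALSE])
  min(cost)
}

# literal Weir & Cockerham (1984) two-population theta from diploid genotype
# vectors (0/1/2), combined over sites as a ratio of sums
oracle_wc_fst <- function(geno_a, geno_b) {
  num <- den <- 0
  for (s in seq_len(nrow(geno_a))) {
    ga <- geno_a[s, ]; gb <- geno_b[s, ]
    n1 <- length(ga); n2 <- length(gb)
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    h1 <- mean(ga == 1); h2 <- mean(gb == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
           hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  num / den
}

# per-site double loop for Patterson's D
oracle_d_stat <- function(p1, p2, p3, pO) {
  abba <- baba <- 0
  for (i in seq_along(p1)) {
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i] * (1 - pO[i])
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i] * (1 - pO[i])
  }
  (abba - baba) / (abba + baba)
}

# Kruskal's algorithm with union-find, exhaustive edge sort
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- which(upper.tri(d), arr.ind = TRUE)
  edges <- edges[order(d[edges]), , drop = FALSE]
  total <- 0; added <- 0
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + d[edges[k, 1], edges[k, 2]]
      added <- added + 1
      if (added == n - 1) break
    }
  }
  total
}

# quadratic interval union per (haplotype, source): repeatedly merge any two
# intervals that overlap or touch within max_gap
oracle_merge_tracts <- function(tracts, max_gap = 0) {
  key <- paste(tracts$haplotype, tracts$contig, tracts$source)
  res <- list()
  for (k in unique(key)) {
    iv <- tracts[key == k, c("start", "end")]
    changed <- TRUE
    while (changed && nrow(iv) > 1) {
      changed <- FALSE
      for (i in seq_len(nrow(iv) - 1)) {
        for (j in seq(i + 1, nrow(iv))) {
          if (iv$start[j] <= iv$end[i] + max_gap &&
              iv$start[i] <= iv$end[j] + max_gap) {
            iv$start[i] <- min(iv$start[i], iv$start[j])
            iv$end[i] <- max(iv$end[i], iv$end[j])
            iv <- iv[-j, , drop = FALSE]
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    first <- which(key == k)[1]
    res[[k]] <- data.frame(haplotype = tracts$haplotype[first],
                           contig = tracts$contig[first],
                           start = iv$start, end = iv$end,
                           source = tracts$source[first],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out[order(out$haplotype, out$contig, out$start), ]
}

# quadratic interval intersection counts
oracle_overlap_counts <- function(a, b, min_overlap = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    n <- 0L
    for (j in seq_len(nrow(b))) {
      if (a$contig[i] == b$contig[j] &&
          min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= min_overlap)
        n <- n + 1L
    }
    n
  }, integer(1))
}
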