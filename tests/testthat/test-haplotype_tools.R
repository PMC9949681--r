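region_from_matrix <- function(haps) {
  # haps: haplotypes x sites
  structure(list(contig = "chr1", start = 0, end = 1000 * (ncol(haps) + 1),
                 positions = seq_len(ncol(haps)) * 1000,
                 haps = haps,
                 hap_ids = paste0("s", rep(seq_len(nrow(haps) / 2), each = 2),
                                  c("_h1", "_h2")),
                 hap_sample = paste0("s", rep(seq_len(nrow(haps) / 2), each = 2))),
            class = "region_haplotypes")
}

test_that("region extraction removes sites at MAF <= cutoff", {
  # 20 haplotypes; site MAFs 0.05 (boundary), 0.10, 0.45, 0
  al <- rbind(c(rep(1L, 1), rep(0L, 19)),
              c(rep(1L, 2), rep(0L, 18)),
              c(rep(1L, 9), rep(0L, 11)),
              rep(0L, 20))
  panel <- toy_panel(al)
  rh <- extract_region(panel, "chr1", 0, 1000)
  expect_equal(length(rh$positions), 2)  # MAF 0.05 removed by the <= rule
  expect_equal(rh$positions, c(200, 300))
  # brute-force MAF filter agrees
  maf <- pmin(rowMeans(al), 1 - rowMeans(al))
  expect_equal(length(rh$positions), sum(maf > 0.05))
  expect_error(extract_region(panel, "chr1", 0, 150), "monomorphic")
  # filtering a pre-extracted region commutes with extracting at the cutoff
  rh0 <- extract_region(panel, "chr1", 0, 1000, maf_min = 0)
  keep <- pmin(colMeans(rh0$haps), 1 - colMeans(rh0$haps)) > 0.05
  expect_equal(unname(rh0$haps[, keep]), unname(rh$haps))
})

test_that("recombinant screening flags constructed chimeras", {
  set.seed(8)
  consA <- rbinom(40, 1, 0.5)
  consB <- 1L - consA                         # maximally divergent
  consC <- consA
  consC[seq(2, 40, 2)] <- 1L - consC[seq(2, 40, 2)]  # differs at every even site
  build <- function(v, n) matrix(rep(v, n), nrow = n, byrow = TRUE)
  chimera <- c(consA[1:20], consB[21:40])
  haps <- rbind(build(consA, 10), build(consB, 8), build(consC, 6), chimera,
                consA)  # 26 haplotypes: last two are one kept + one chimera
  rh <- region_from_matrix(haps)
  res <- screen_recombinants(rh)
  expect_true(rh$hap_ids[25] %in% res$flagged)   # the chimera
  expect_true(rh$hap_ids[26] %in% res$kept)      # identical to consensus A
  expect_equal(length(res$kept) + length(res$flagged), 26)

  # recall over many simulated crossovers at default settings
  set.seed(18)
  hits <- 0; n_chim <- 40
  for (i in seq_len(n_chim)) {
    bp <- sample(10:30, 1)
    ch <- if (i %% 2 == 0) c(consA[1:bp], consB[(bp + 1):40]) else
      c(consB[1:bp], consC[(bp + 1):40])
    haps_i <- rbind(build(consA, 6), build(consB, 6), build(consC, 6), ch)
    res_i <- screen_recombinants(region_from_matrix(haps_i))
    if (region_from_matrix(haps_i)$hap_ids[19] %in% res_i$flagged)
      hits <- hits + 1
  }
  expect_gte(hits / n_chim, 0.9)

  expect_warning(screen_recombinants(region_from_matrix(build(consA, 4)),
                                     k_major = 3), "distinct")
})

test_that("haplogroup clustering recovers planted groups, is order-invariant", {
  set.seed(44)
  centers <- list(rbinom(60, 1, 0.5), rbinom(60, 1, 0.5), rbinom(60, 1, 0.5))
  # ensure centers are well separated (Hamming >> cutoff 3)
  centers[[2]] <- 1L - centers[[1]]
  centers[[3]][1:30] <- 1L - centers[[1]][1:30]; centers[[3]][31:60] <- centers[[1]][31:60]
  mutate <- function(v) { i <- sample(60, 1); v[i] <- 1L - v[i]; v }
  haps <- do.call(rbind, c(
    lapply(1:10, function(i) mutate(centers[[1]])),
    lapply(1:6, function(i) mutate(centers[[2]])),
    lapply(1:4, function(i) mutate(centers[[3]]))))
  rh <- region_from_matrix(haps)
  cl <- cluster_haplogroups(rh)
  expect_equal(sort(unique(cl$group)), c("hap-1", "hap-2", "hap-3"))
  expect_equal(unname(table(cl$group)[paste0("hap-", 1:3)]),
               array(c(10L, 6L, 4L)), ignore_attr = TRUE)
  expect_equal(cl$group[1:10], rep("hap-1", 10))

  # permutation invariance of memberships
  perm <- sample(nrow(haps))
  cl2 <- cluster_haplogroups(region_from_matrix(haps[perm, ]))
  same <- outer(cl$group[perm], cl$group[perm], "==")
  same2 <- outer(cl2$group, cl2$group, "==")
  expect_true(all(same == same2))

  one <- cluster_haplogroups(region_from_matrix(
    matrix(rep(centers[[1]], 6), nrow = 6, byrow = TRUE)))
  expect_true(all(one$group == "hap-1"))
})

test_that("haplogroup frequency tables reproduce the published worked values", {
  # 1831 haplotypes across two breeds, 155 carriers of hap-1 overall;
  # Duolang: 63 of 68 carry hap-2
  n_all <- 1831; n_duolang <- 68
  hap_ids <- paste0("s", rep(seq_len(ceiling(n_all / 2)), each = 2),
                    c("_h1", "_h2"))[seq_len(n_all)]
  grp <- c(rep("hap-1", 155), rep("hap-2", n_all - 155))
  samp <- unique(sub("_h[12]$", "", hap_ids))
  # Duolang: 34 complete samples (68 haplotypes), 63 of which carry hap-2
  duolang <- samp[882:915]
  duo_rows <- which(sub("_h[12]$", "", hap_ids) %in% duolang)
  stopifnot(length(duo_rows) == n_duolang)
  grp[duo_rows[1:5]] <- "hap-3"
  groups <- data.frame(haplotype = hap_ids, group = grp,
                       stringsAsFactors = FALSE)
  pm <- data.frame(sample = samp,
                   breed = ifelse(samp %in% duolang, "Duolang", "Other"),
                   group = "dom")
  tab <- haplogroup_frequencies(groups, pm)
  expect_equal(tab$frequency[tab$group == "hap-1" & tab$breed == "ALL"], 0.085)
  expect_equal(tab$fraction[tab$group == "hap-1" & tab$breed == "ALL"], "155/1831")
  expect_equal(tab$frequency[tab$group == "hap-2" & tab$breed == "Duolang"], 0.926)
  expect_equal(tab$frequency[tab$group == "hap-1" & tab$breed == "Duolang"], 0)
  # row sums per breed equal the breed haplotype counts
  duo <- tab[tab$breed == "Duolang", ]
  expect_equal(sum(duo$carriers), unique(duo$haplotypes))
  expect_equal(unique(duo$haplotypes), n_duolang)
})

test_that("haplotype networks: edges, star topology, MST equals Kruskal oracle", {
  h <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L))
  net <- build_network(h)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)

  # star: center plus 4 one-step variants (distance 2 between leaves)
  center <- rep(0L, 8)
  leaves <- diag(1L, 4, 8)
  net <- build_network(rbind(center, leaves, center, center))
  expect_equal(sum(net$nodes$multiplicity), 7)  # multiplicities sum to input
  expect_equal(net$nodes$multiplicity[1], 3)
  mst <- net$edges[net$edges$in_mst, ]
  expect_equal(nrow(mst), 4)
  expect_true(all(mst$from == "N1" | mst$to == "N1"))
  expect_true(all(mst$weight == 1))

  set.seed(55)
  for (rep in 1:5) {
    h <- matrix(rbinom(12 * 30, 1, 0.5), nrow = 12)
    h <- h[!duplicated(apply(h, 1, paste, collapse = "")), ]
    net <- build_network(h)
    expect_equal(sum(net$edges$weight[net$edges$in_mst]),
                 oracle_mst_weight(net$dist))
    expect_equal(sum(net$edges$in_mst), nrow(net$dist) - 1)
  }
  expect_error(build_network(rbind(center, center)), "distinct")
})

test_that("networks on fixture region haplotypes are internally consistent", {
  sim <- intro_sim()
  rh <- extract_region(sim$panel, "chr1", 0, 2e5)
  res <- screen_recombinants(rh)
  cl <- cluster_haplogroups(rh, hap_ids = res$kept)
  tab <- haplogroup_frequencies(cl, sim$popmap)
  all_rows <- tab[tab$breed == "ALL", ]
  expect_equal(sum(all_rows$carriers), length(res$kept))
  net <- build_network(rh)
  expect_equal(sum(net$nodes$multiplicity), length(rh$hap_ids))
})
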