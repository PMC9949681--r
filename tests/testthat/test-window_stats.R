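test_that("F_ST is ~0 for identical balanced groups and 1 at fixed differences", {
  # two groups x 2 samples, every sample heterozygous: p = 0.5 everywhere
  het <- matrix(rep(c(0L, 1L), times = 4 * 3), nrow = 3, byrow = TRUE)
  panel <- toy_panel(het)
  pm <- toy_popmap(panel, rep(c("A", "B"), each = 2))
  win <- list(contig = "chr1", start = 0, end = 1000)
  expect_lt(abs(fst_window(panel, pm, "A", "B", win, min_sites = 1)), 1e-12)

  fixed <- rbind(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                 c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                 c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  panel <- toy_panel(fixed)
  pm <- toy_popmap(panel, rep(c("A", "B"), each = 2))
  expect_equal(fst_window(panel, pm, "A", "B", win, min_sites = 1), 1.0)
})

test_that("windowed F_ST equals the literal Weir-Cockerham ratio of sums", {
  set.seed(31)
  for (rep in 1:20) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1); ns <- sample(3:8, 1)
    al <- matrix(rbinom(ns * 2 * (nA + nB), 1, runif(ns)), nrow = ns)
    # avoid monomorphic sites (0/0 oracle terms are fine but uninformative)
    panel <- toy_panel(al)
    pm <- toy_popmap(panel, rep(c("A", "B"), times = c(nA, nB)))
    got <- fst_window(panel, pm, "A", "B",
                      list(contig = "chr1", start = 0, end = 1e5), min_sites = 1)
    idx_a <- seq_len(2 * nA); idx_b <- 2 * nA + seq_len(2 * nB)
    geno <- function(cols) {
      i1 <- cols[seq(1, length(cols), 2)]
      al[, i1, drop = FALSE] + al[, i1 + 1, drop = FALSE]
    }
    want <- oracle_wc_fst(geno(idx_a), geno(idx_b))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("F_ST is symmetric and the Hudson option agrees in sign", {
  sim <- intro_sim()
  win <- list(contig = "chr1", start = 0, end = 5e4)
  ab <- fst_window(sim$panel, sim$popmap, "dom_a", "urial", win)
  ba <- fst_window(sim$panel, sim$popmap, "urial", "dom_a", win)
  expect_equal(ab, ba, tolerance = 1e-12)
  hud <- fst_window(sim$panel, sim$popmap, "dom_a", "urial", win,
                    estimator = "hudson")
  expect_gt(ab, 0); expect_gt(hud, 0)
})

test_that("d_XY matches hand sums and is symmetric", {
  expect_equal(dxy_window(c(1, 1), c(1, 1), 50000), 0)
  expect_equal(dxy_window(1, 0, 50000), 2e-5)
  # 3-site toy: 0.2*0.2+0.8*0.8 = 0.68; 0.5; 1  -> 2.18 over 10 kb
  pA <- c(0.2, 0.5, 1); pB <- c(0.8, 0.5, 0)
  expect_equal(dxy_window(pA, pB, 10000), 2.18e-4)
  expect_equal(dxy_window(pA, pB, 10000), dxy_window(pB, pA, 10000))
  expect_equal(dxy_window(numeric(0), numeric(0), 1000), 0)
})

test_that("Patterson's D matches the per-site double-loop oracle", {
  p <- runif(5)
  expect_equal(d_stat_window(p, p, runif(5), runif(5)), 0)  # p1 = p2 symmetry
  expect_equal(d_stat_window(0, 1, 1, 0), 1)                # single ABBA site
  expect_true(is.na(d_stat_window(0, 0, 0, 0)))             # empty denominator
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    p1 <- runif(n); p2 <- runif(n); p3 <- runif(n); pO <- runif(n, 0, 0.3)
    expect_equal(d_stat_window(p1, p2, p3, pO), oracle_d_stat(p1, p2, p3, pO),
                 tolerance = 1e-12)
    expect_gte(d_stat_window(p1, p2, p3, pO), -1)
    expect_lte(d_stat_window(p1, p2, p3, pO), 1)
  }
})

test_that("f_d follows the dynamic-donor definition", {
  # donor equals recipient excess: P2 = P3 (and D > 0) gives exactly 1
  p2 <- c(0.9, 0.7, 0.8); p1 <- c(0.1, 0.2, 0.1); pO <- c(0, 0, 0.05)
  expect_equal(fd_window(p1, p2, p2, pO), 1.0)
  # P1 = P2: the ABBA and BABA sums cancel site by site, numerator 0
  expect_equal(fd_window(p2, p2, c(0.6, 0.9, 0.5), pO), 0.0)
  # hand computation with the per-site max rule (p2 < p3 at site 2)
  p1 <- c(0.1, 0.2, 0.0); p2 <- c(0.8, 0.3, 0.5); p3 <- c(0.6, 0.9, 0.5)
  pO <- c(0, 0, 0.05)
  expect_equal(fd_window(p1, p2, p3, pO), 0.7475 / 1.4275, tolerance = 1e-12)
  # negative-D window reports NA
  expect_true(is.na(fd_window(c(1, 1), c(0, 0), c(1, 1), c(0, 0))))
})

test_that("z_scan standardizes, applies the requested tail and flags P<0.001", {
  v <- c(1, 2, 3)
  res <- z_scan(v, "two")
  expect_equal(res$p[2], 1)  # at the mean
  expect_equal(res$z, (v - mean(v)) / sd(v))
  set.seed(9)
  v <- rnorm(200)
  up <- z_scan(v, "upper")
  expect_equal(up$p, pnorm(up$z, lower.tail = FALSE))
  two <- z_scan(v, "two")
  expect_equal(two$p, 2 * pnorm(-abs(two$z)))
  expect_equal(two$sig, two$p < 0.001)
  expect_warning(res <- z_scan(rep(2, 10)), "constant")
  expect_true(all(res$p == 1))
  expect_error(z_scan(c(1, NA, NA)), "non-NA")
})

test_that("permutation threshold: identical populations give ~0, determinism,
           and real introgression scans exceed it", {
  # wild group = exact copies of domestic samples (one population relabelled)
  sim <- simulate_panel(sim_config(pop_tree = data.frame(
    node = c("root", "popA"), parent = c(NA, "root"), time = c(1e4, 1e4)),
    n_haplotypes_per_pop = c(popA = 264L), contig_length = 1e6, seed = 3))
  al <- sim$panel$alleles
  al[, 133:264] <- al[, 1:132]
  panel <- haplotype_panel(sim$panel$contigs, sim$panel$sites, al,
                           sim$panel$sample_ids)
  pm <- data.frame(sample = panel$sample_ids, breed = "x",
                   group = rep(c("dom", "wild"), each = 66))
  thr <- fst_permutation_threshold(panel, pm, "dom", "wild", n_draw = 33,
                                   reps = 10, seed = 5)
  expect_lte(thr, 0.02)
  t1 <- fst_permutation_threshold(panel, pm, "dom", "wild", n_draw = 33,
                                  reps = 1, seed = 9)
  t2 <- fst_permutation_threshold(panel, pm, "dom", "wild", n_draw = 33,
                                  reps = 1, seed = 9)
  expect_identical(t1, t2)
  expect_error(fst_permutation_threshold(panel, pm, "dom", "wild",
                                         n_draw = 100, reps = 1), "n_draw")

  # on the introgression fixture the permutation threshold sits far below the
  # top percentile of the real domestic-vs-donor scan
  simi <- intro_sim()
  thr_real <- fst_permutation_threshold(simi$panel, simi$popmap,
    c("dom_a", "dom_b", "dom_c", "dom_d"), "urial", n_draw = 8, reps = 5,
    seed = 1)
  top1 <- stats::quantile(intro_scan()$fst, 0.99, na.rm = TRUE)
  expect_lt(thr_real, top1)
})

test_that("scan table is consistent and d_XY/F_ST behave on the fixture", {
  sc <- intro_scan()
  expect_true(all(c("fst", "dxy", "d", "fd", "p_fd", "p_fst") %in% names(sc)))
  expect_true(all(sc$dxy >= 0, na.rm = TRUE))
  expect_true(all(sc$d >= -1 & sc$d <= 1, na.rm = TRUE))
  expect_true(all(sc$n_sites[!sc$clipped] >= 0))
  # f_d NA exactly where D < 0 (or too few sites)
  expect_true(all(is.na(sc$fd[!is.na(sc$d) & sc$d < 0])))
})
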