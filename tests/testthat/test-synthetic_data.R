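small_tree <- function() {
  data.frame(node = c("root", "outgroup", "urial", "anc_dom", "eu_ref", "dom_a"),
             parent = c(NA, "root", "root", "root", "anc_dom", "anc_dom"),
             time = c(6e6, 6e6, 1.26e6, 1.1e4, 1.1e4, 1.1e4),
             stringsAsFactors = FALSE)
}

small_haps <- c(outgroup = 4L, urial = 8L, eu_ref = 8L, dom_a = 20L)

test_that("config validation rejects inconsistent inputs", {
  expect_error(sim_config(n_haplotypes_per_pop = c(dom_a = 0L)), "positive")
  expect_error(sim_config(n_haplotypes_per_pop = c(dom_a = 3L)), "even")
  expect_error(sim_config(n_haplotypes_per_pop = c(nosuchpop = 4L)), "pop_tree")
  expect_error(
    sim_config(pop_tree = small_tree(), n_haplotypes_per_pop = small_haps,
               pulses = list(list(donor = "ghost", recipient = "dom_a",
                                  admix_time_years = 100, admix_fraction = 0.1))),
    "donor")
  # admixture older than the donor/recipient divergence is impossible
  expect_error(
    sim_config(pop_tree = small_tree(), n_haplotypes_per_pop = small_haps,
               pulses = list(list(donor = "urial", recipient = "dom_a",
                                  admix_time_years = 2e6, admix_fraction = 0.1))),
    "divergence")
})

test_that("no pulses means no truth tracts and a clean panel", {
  sim <- simulate_panel(sim_config(pop_tree = small_tree(),
                                   n_haplotypes_per_pop = small_haps,
                                   contig_length = 5e5, seed = 3))
  expect_equal(nrow(sim$truth), 0)
  expect_equal(length(sim$panel$hap_ids), sum(small_haps))
  expect_true(all(diff(sim$panel$sites$pos) > 0))
  # panel holds only segregating biallelic sites
  p <- rowMeans(sim$panel$alleles)
  expect_true(all(p > 0 & p < 1))
})

test_that("complete replacement limit: admix_fraction 1 covers the genome", {
  cfg <- sim_config(pop_tree = small_tree(), n_haplotypes_per_pop = small_haps,
                    contig_length = 5e5, seed = 4,
                    pulses = list(list(donor = "urial", recipient = "dom_a",
                                       admix_time_years = 100,
                                       admix_fraction = 1)))
  sim <- simulate_panel(cfg)
  cov <- sum(sim$truth$length) / (small_haps[["dom_a"]] * 5e5)
  expect_gte(cov, 0.95)
})

test_that("truth tract lengths match the exponential admixture-tract model", {
  # divergence 1.26 Ma donor, pulse 40 ka at fraction 0.1 on a 1-Mb contig:
  # expected tract length 1/(r * t_gen) = 10 kb (to first order in the
  # admixture fraction)
  haps <- c(outgroup = 4L, urial = 8L, eu_ref = 8L, dom_a = 26L)
  cfg <- sim_config(pop_tree = small_tree(), n_haplotypes_per_pop = haps,
                    contig_length = 1e6, mutation_density = 2e-4, seed = 7,
                    pulses = list(list(donor = "urial", recipient = "dom_a",
                                       admix_time_years = 4e4,
                                       admix_fraction = 0.1)))
  sim <- simulate_panel(cfg)
  len <- sim$truth$length
  expect_gte(length(len), 200)
  mc_se <- stats::sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 10000), 2 * mc_se)
  # exact model: donor tracts are Exp with rate (1-alpha) r t, mean 11,111 bp
  expect_lt(abs(mean(len) - 1 / (0.9 * 1e-8 * 1e4)), 2 * mc_se)
})

test_that("truth tracts never overlap, stay in bounds, and realized donor
           fraction matches the admixture fraction", {
  sim <- intro_sim()
  cfg_len <- sim$panel$contigs$length[1]
  by_hap <- split(sim$truth, sim$truth$haplotype)
  for (df in by_hap) {
    df <- df[order(df$start), ]
    expect_true(all(df$end > df$start))
    expect_true(all(df$start >= 0 & df$end <= cfg_len))
    if (nrow(df) > 1) expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
  }
  rec_haps <- paste0(rep(sprintf("dom_a_%02d", 1:10), each = 2), c("_h1", "_h2"))
  cov <- vapply(rec_haps, function(h)
    sum(sim$truth$length[sim$truth$haplotype == h]) / cfg_len, numeric(1))
  mc_se <- stats::sd(cov) / sqrt(length(cov))
  expect_lt(abs(mean(cov) - 0.1), 3 * mc_se)
})

test_that("F2 cross: null effect gives no causal association, noise-free
           monogenic trait is ordered by causal genotype", {
  sim <- simulate_panel(sim_config_f2(5))
  causal <- select_causal_site(sim$panel)
  sim$panel <- plant_causal_site(sim$panel, sim$popmap, causal,
                                 c(friesian = 0.9, hu = 0.1), seed = 5)
  null_f2 <- simulate_f2_cross(sim$panel, sim$popmap, c("friesian", "hu"),
                               causal, beta = 0, h2 = 0.3, n_f2 = 200, seed = 5)
  fit <- summary(stats::lm(null_f2$phenotype$trait ~ null_f2$genotypes$G[, causal]))
  expect_lt(abs(fit$coefficients[2, 1]), 3 * fit$coefficients[2, 2])

  mono <- simulate_f2_cross(sim$panel, sim$popmap, c("friesian", "hu"),
                            causal, beta = 1, h2 = 0.999, n_f2 = 200, seed = 5,
                            polygenic_ratio = 0)
  g <- mono$genotypes$G[, causal]
  y <- mono$phenotype$trait
  expect_true(max(y[g == 0]) < min(y[g == 1]))
  expect_true(max(y[g == 1]) < min(y[g == 2]))

  expect_error(simulate_f2_cross(sim$panel, sim$popmap, c("friesian", "hu"),
                                 causal, 0.5, h2 = 1.2, n_f2 = 50), "h2")
})

test_that("fixture suite is seed-deterministic and differs across seeds", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  d3 <- file.path(tempdir(), "fx3")
  p1 <- generate_fixture_suite(d1, seed = 1)
  p2 <- generate_fixture_suite(d2, seed = 1)
  p3 <- generate_fixture_suite(d3, seed = 2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[k])), unname(tools::md5sum(p2[k])),
                     label = paste("seed-1 determinism for", k))
  }
  expect_false(identical(unname(tools::md5sum(p1["vcf"])),
                         unname(tools::md5sum(p3["vcf"]))))
  # the written panel round-trips
  panel <- read_phased_vcf(p1["vcf"])
  popmap <- read_popmap(p1["popmap"])
  expect_silent(validate_popmap(panel, popmap))
  truth <- read_tracts_bed(p1["truth"])
  expect_true(all(truth$end > truth$start))
})
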