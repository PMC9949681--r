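# Shared fixtures, built once per test run and cached (several test files and
# the acceptance suite reuse the same simulated panels).

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, expr, envir = fixture_cache)
  get(key, envir = fixture_cache)
}

intro_sim <- function() cached("intro", simulate_panel(sim_config_introgression(7)))

null_sim <- function() cached("null",
  simulate_panel(sim_config(pulses = list(), seed = 7)))

null_big_sim <- function() cached("null_big", simulate_panel(sim_config_null(seed = 7)))

outlier_sim <- function() cached("outlier", simulate_panel(sim_config_outlier(7)))

lai_sources <- c("eu_ref", "urial", "argali")

intro_lai <- function() cached("intro_lai", {
  s <- intro_sim()
  infer_tracts(s$panel, s$popmap, "dom_a", lai_sources)
})

intro_scan <- function() cached("intro_scan", {
  s <- intro_sim()
  scan_windows(s$panel, s$popmap, "eu_ref", "dom_a", "urial", "outgroup")
})

null_big_scan <- function() cached("null_big_scan", {
  s <- null_big_sim()
  scan_windows(s$panel, s$popmap, "eu_ref", "dom_a", "urial", "outgroup")
})

outlier_lai <- function() cached("outlier_lai", {
  s <- outlier_sim()
  rbind(infer_tracts(s$panel, s$popmap, "dom_a", lai_sources),
        infer_tracts(s$panel, s$popmap, "dom_b", lai_sources))
})

# One F2 replicate: simulate founders, plant the causal site, cross, QC, scan.
f2_replicate <- function(seed, beta = 0.8, h2 = 0.4, n_f2 = 300) {
  sim <- simulate_panel(sim_config_f2(seed))
  causal <- select_causal_site(sim$panel)
  sim$panel <- plant_causal_site(sim$panel, sim$popmap, causal,
                                 c(friesian = 0.9, hu = 0.1), seed = seed)
  f2 <- simulate_f2_cross(sim$panel, sim$popmap, c("friesian", "hu"), causal,
                          beta = beta, h2 = h2, n_f2 = n_f2, seed = seed)
  gt <- suppressMessages(qc_filter(f2$genotypes))
  list(sim = sim, f2 = f2, gt = gt, causal_pos = sim$panel$sites$pos[causal])
}

f2_fix <- function() cached("f2_fix", f2_replicate(11))

# Small hand-built panel: alleles is a sites x haplotypes matrix (haplotypes
# in sample order, 2 per sample).
toy_panel <- function(alleles, pos = NULL, contig_len = NULL, contig = "chr1") {
  alleles <- as.matrix(alleles)
  ns <- ncol(alleles) / 2
  if (is.null(pos)) pos <- seq_len(nrow(alleles)) * 100
  if (is.null(contig_len)) contig_len <- max(pos) + 100
  haplotype_panel(data.frame(contig = contig, length = contig_len),
                  data.frame(contig = contig, pos = pos),
                  alleles, sprintf("s%02d", seq_len(ns)))
}

toy_popmap <- function(panel, groups) {
  data.frame(sample = panel$sample_ids, breed = groups, group = groups,
             stringsAsFactors = FALSE)
}

# windows overlapping any ground-truth tract
affected_windows <- function(scan, truth) {
  vapply(seq_len(nrow(scan)), function(i) {
    any(truth$contig == scan$contig[i] &
        truth$start < scan$end[i] & truth$end > scan$start[i])
  }, logical(1))
}
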