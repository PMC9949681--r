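#' Simulation configuration for synthetic phased panels
#'
#' Describes a population tree (one outgroup, wild donor populations, domestic
#' recipient populations), per-population haplotype counts, and optional
#' admixture pulses from donors into recipients.  Allele-frequency divergence
#' between populations is generated by per-branch drift on the logit scale
#' with variance proportional to branch length in years (`drift_rate`); this
#' is a deliberately cheap stand-in for a coalescent that preserves the
#' tree-structured covariance the window statistics rely on.
#'
#' @param pop_tree data.frame with columns `node`, `parent` (`NA` for the
#'   root) and `time` (years ago at which the node's lineage split from its
#'   parent).  Leaves are the nodes named in `n_haplotypes_per_pop`; other
#'   rows are internal nodes.
#' @param n_haplotypes_per_pop named integer vector, haplotypes per leaf
#'   population (must be even: two haplotypes per sample).
#' @param contig_length contig length in bp.
#' @param n_contigs number of contigs.
#' @param mutation_density expected segregating sites per bp.
#' @param gen_time generation time in years (default 4).
#' @param recomb_rate recombination rate per bp per generation (default 1e-8).
#' @param drift_rate logit-scale drift variance per year of branch length.
#' @param pulses list of admixture pulses, each a list with elements `donor`,
#'   `recipient`, `admix_time_years`, `admix_fraction`.
#' @param seed integer seed; all randomness in [simulate_panel()] flows from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(pop_tree = sim_pop_tree_default(),
                       n_haplotypes_per_pop = sim_haps_default(),
                       contig_length = 3e6, n_contigs = 1L,
                       mutation_density = 3e-3, gen_time = 4,
                       recomb_rate = 1e-8, drift_rate = 3e-6,
                       pulses = list(), seed = 1L) {
  stopifnot(is.data.frame(pop_tree),
            all(c("node", "parent", "time") %in% names(pop_tree)))
  if (sum(is.na(pop_tree$parent)) != 1L) stop("pop_tree must have exactly one root")
  if (any(pop_tree$time <= 0)) stop("divergence times must be strictly positive")
  for (i in seq_len(nrow(pop_tree))) {
    par <- pop_tree$parent[i]
    if (is.na(par)) next
    j <- match(par, pop_tree$node)
    if (is.na(j)) stop("pop_tree parent not found: ", par)
    if (pop_tree$time[i] > pop_tree$time[j])
      stop("child divergence time must not exceed parent time: ", pop_tree$node[i])
  }
  if (is.null(names(n_haplotypes_per_pop)) || any(n_haplotypes_per_pop <= 0))
    stop("n_haplotypes_per_pop must be a named vector of positive counts")
  if (any(n_haplotypes_per_pop %% 2 != 0))
    stop("haplotype counts must be even (two per sample)")
  missing_leaf <- setdiff(names(n_haplotypes_per_pop), pop_tree$node)
  if (length(missing_leaf)) stop("population not in pop_tree: ",
                                 paste(missing_leaf, collapse = ", "))
  for (p in pulses) {
    stopifnot(all(c("donor", "recipient", "admix_time_years", "admix_fraction")
                  %in% names(p)))
    if (!p$donor %in% names(n_haplotypes_per_pop))
      stop("pulse donor is not a sampled population: ", p$donor)
    if (!p$recipient %in% names(n_haplotypes_per_pop))
      stop("pulse recipient is not a sampled population: ", p$recipient)
    if (p$admix_fraction <= 0 || p$admix_fraction > 1)
      stop("admix_fraction must be in (0, 1]")
    tmrca <- tree_mrca_time(pop_tree, p$donor, p$recipient)
    if (p$admix_time_years >= tmrca)
      stop("admix_time must predate the donor/recipient divergence (",
           tmrca, " years)")
  }
  structure(list(pop_tree = pop_tree,
                 n_haplotypes_per_pop = n_haplotypes_per_pop,
                 contig_length = contig_length, n_contigs = as.integer(n_contigs),
                 mutation_density = mutation_density, gen_time = gen_time,
                 recomb_rate = recomb_rate, drift_rate = drift_rate,
                 pulses = pulses, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default population tree for the study fixtures
#'
#' An outgroup (6.0 Ma), two wild donors at the divergence times used for the
#' ILS filter (argali 2.36 Ma, urial 1.26 Ma), a non-introgressed domestic
#' reference group and four recipient meta-populations radiating at
#' domestication (11 ka).
#' @return data.frame usable as the `pop_tree` of [sim_config()].
#' @export
sim_pop_tree_default <- function() {
  data.frame(
    node   = c("root", "outgroup", "anc_argali", "argali", "anc_urial",
               "urial", "anc_dom", "eu_ref", "dom_a", "dom_b", "dom_c", "dom_d"),
    parent = c(NA, "root", "root", "anc_argali", "anc_argali",
               "anc_urial", "anc_urial", rep("anc_dom", 5)),
    time   = c(6.0e6, 6.0e6, 2.36e6, 2.36e6, 1.26e6,
               1.26e6, 1.1e4, rep(1.1e4, 5)),
    stringsAsFactors = FALSE)
}

#' Default haplotype counts per population
#' @return named integer vector.
#' @export
sim_haps_default <- function() {
  c(outgroup = 12L, argali = 16L, urial = 16L, eu_ref = 30L,
    dom_a = 20L, dom_b = 20L, dom_c = 20L, dom_d = 20L)
}

#' Ready-made configuration: one urial pulse into one meta-population
#'
#' The default study condition for tract-level validation: admixture fraction
#' 0.1 from urial into `dom_a` 3,000 years ago (750 generations), giving donor
#' tracts with mean length about 148 kb, long enough that most exceed the
#' 50-kb window size.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
sim_config_introgression <- function(seed = 1L) {
  sim_config(pulses = list(list(donor = "urial", recipient = "dom_a",
                                admix_time_years = 3000, admix_fraction = 0.1)),
             seed = seed)
}

#' Ready-made configuration: no admixture (null fixture)
#' @param seed integer seed.
#' @param contig_length contig length (default 5 Mb for window-level
#'   calibration checks).
#' @param n_contigs number of contigs (default 2).
#' @return a `sim_config`.
#' @export
sim_config_null <- function(seed = 1L, contig_length = 5e6, n_contigs = 2L) {
  sim_config(contig_length = contig_length, n_contigs = n_contigs,
             pulses = list(), seed = seed)
}

#' Ready-made configuration: strong pulse for outlier-tract recovery
#'
#' Admixture fraction 0.6 from urial into `dom_a` 800 years ago (200
#' generations): donor tracts with mean length about 1.25 Mb, mimicking a
#' locus swept to high frequency in a single meta-population.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
sim_config_outlier <- function(seed = 1L) {
  sim_config(pulses = list(list(donor = "urial", recipient = "dom_a",
                                admix_time_years = 800, admix_fraction = 0.6)),
             seed = seed)
}

#' Ready-made configuration: two recently diverged founder breeds for F2 crosses
#'
#' Two breeds split 10 ka, 2-Mb contig, used as founders for
#' [simulate_f2_cross()].
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
sim_config_f2 <- function(seed = 1L) {
  tree <- data.frame(node = c("root", "friesian", "hu"),
                     parent = c(NA, "root", "root"),
                     time = c(1e4, 1e4, 1e4), stringsAsFactors = FALSE)
  sim_config(pop_tree = tree,
             n_haplotypes_per_pop = c(friesian = 40L, hu = 40L),
             contig_length = 2e6, mutation_density = 8e-4, seed = seed)
}

# time at which the lineages of a and b separated: the later-branching of the
# two path nodes immediately below their most recent shared ancestor
tree_mrca_time <- function(pop_tree, a, b) {
  path <- function(x) {
    out <- character()
    while (!is.na(x)) { out <- c(out, x); x <- pop_tree$parent[match(x, pop_tree$node)] }
    out
  }
  pa <- path(a); pb <- path(b)
  shared <- intersect(pa, pb)
  last_a <- utils::tail(setdiff(pa, shared), 1)
  last_b <- utils::tail(setdiff(pb, shared), 1)
  if (!length(last_a) && !length(last_b))
    return(min(pop_tree$time[match(shared, pop_tree$node)]))
  max(pop_tree$time[match(c(last_a, last_b), pop_tree$node)])
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# per-branch drift on logit scale; eps keeps logit finite
drift_freqs <- function(p, var, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  expit(logit(p) + stats::rnorm(length(p), 0, sqrt(var)))
}

# present-day allele frequencies for every leaf, via recursion over the tree
sim_tree_freqs <- function(pop_tree, leaves, n_sites, drift_rate, p_anc) {
  birth <- list()
  root <- pop_tree$node[is.na(pop_tree$parent)]
  birth[[root]] <- p_anc
  remaining <- setdiff(pop_tree$node, root)
  while (length(remaining)) {
    for (nd in remaining) {
      par <- pop_tree$parent[match(nd, pop_tree$node)]
      if (!is.null(birth[[par]])) {
        dt <- pop_tree$time[match(par, pop_tree$node)] -
              pop_tree$time[match(nd, pop_tree$node)]
        birth[[nd]] <- drift_freqs(birth[[par]], drift_rate * dt)
        remaining <- setdiff(remaining, nd)
      }
    }
  }
  out <- lapply(leaves, function(nd) {
    drift_freqs(birth[[nd]], drift_rate * pop_tree$time[match(nd, pop_tree$node)])
  })
  stats::setNames(out, leaves)
}

# Two-state Markov admixture-tract model along a chromosome: donor segments
# are Exp with rate (1-alpha)*r*t generations, recipient gaps Exp with rate
# alpha*r*t, so the stationary donor fraction is exactly alpha.  Returns
# 0-based half-open donor intervals.
sim_tracts_markov <- function(len, alpha, rate_total) {
  if (alpha >= 1) return(data.frame(start = 0, end = len))
  r_out_donor <- (1 - alpha) * rate_total
  r_out_rec <- alpha * rate_total
  pos <- 0
  donor <- stats::runif(1) < alpha
  starts <- ends <- numeric()
  while (pos < len) {
    seg <- stats::rexp(1, if (donor) r_out_donor else r_out_rec)
    if (donor) {
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + seg, len))
    }
    pos <- pos + seg
    donor <- !donor
  }
  data.frame(start = floor(starts), end = ceiling(ends))
}

#' Simulate a phased panel with known introgression tracts
#'
#' Generates per-population allele frequencies by tree-structured drift,
#' samples phased haplotypes, then applies each admixture pulse: every
#' recipient haplotype receives donor segments from a stationary two-state
#' Markov process along the chromosome (donor fraction `admix_fraction`,
#' donor tract lengths exponential with mean
#' `1/((1-admix_fraction) * recomb_rate * admix_time_generations)`, the
#' small-fraction limit of which is the classical `1/(r t)`).  Alleles inside
#' a donor segment are copied from one randomly chosen donor haplotype, and
#' the segment is recorded exactly as a ground-truth tract.  Sites monomorphic
#' across the final panel are dropped.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a [haplotype_panel()]), `truth`
#'   (data.frame of ground-truth tracts: `haplotype`, `contig`, `start`,
#'   `end`, `source`, `length`) and `popmap` (sample/breed/group table; breed
#'   and group equal the population label).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    pops <- names(config$n_haplotypes_per_pop)
    nhap <- config$n_haplotypes_per_pop
    sample_ids <- unlist(lapply(pops, function(p)
      sprintf("%s_%02d", p, seq_len(nhap[[p]] / 2))))
    hap_pop <- rep(pops, times = nhap)
    contigs <- data.frame(contig = paste0("chr", seq_len(config$n_contigs)),
                          length = config$contig_length, stringsAsFactors = FALSE)
    site_list <- list(); allele_list <- list()
    truth <- list()
    for (ci in seq_len(config$n_contigs)) {
      ctg <- contigs$contig[ci]
      n_sites <- max(2L, stats::rpois(1, config$mutation_density * config$contig_length))
      pos <- sort(sample.int(config$contig_length, n_sites)) - 1L
      p_anc <- stats::rbeta(n_sites, 0.5, 3)
      freqs <- sim_tree_freqs(config$pop_tree, pops, n_sites,
                              config$drift_rate, p_anc)
      al <- matrix(0L, n_sites, sum(nhap))
      col <- 1L
      for (p in pops) {
        for (h in seq_len(nhap[[p]])) {
          al[, col] <- stats::rbinom(n_sites, 1L, freqs[[p]])
          col <- col + 1L
        }
      }
      # admixture pulses: overwrite recipient haplotypes with donor copies
      for (pulse in config$pulses) {
        t_gen <- pulse$admix_time_years / config$gen_time
        rate_total <- config$recomb_rate * t_gen
        donor_cols <- which(hap_pop == pulse$donor)
        rec_cols <- which(hap_pop == pulse$recipient)
        for (rc in rec_cols) {
          segs <- sim_tracts_markov(config$contig_length, pulse$admix_fraction,
                                    rate_total)
          if (!nrow(segs)) next
          hap_id <- paste0(sample_ids[ceiling(rc / 2)],
                           c("_h1", "_h2")[(rc - 1) %% 2 + 1])
          for (si in seq_len(nrow(segs))) {
            idx <- which(pos >= segs$start[si] & pos < segs$end[si])
            tmpl <- sample(donor_cols, 1)
            if (length(idx)) al[idx, rc] <- al[idx, tmpl]
          }
          truth[[length(truth) + 1L]] <- data.frame(
            haplotype = hap_id, contig = ctg,
            start = segs$start, end = segs$end, source = pulse$donor,
            stringsAsFactors = FALSE)
        }
      }
      keep <- rowSums(al) > 0 & rowSums(al) < ncol(al)
      site_list[[ci]] <- data.frame(contig = ctg, pos = pos[keep],
                                    stringsAsFactors = FALSE)
      allele_list[[ci]] <- al[keep, , drop = FALSE]
    }
    panel <- haplotype_panel(contigs, do.call(rbind, site_list),
                             do.call(rbind, allele_list), sample_ids)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(haplotype = character(), contig = character(),
                 start = numeric(), end = numeric(), source = character(),
                 stringsAsFactors = FALSE)
    if (nrow(truth)) truth$length <- truth$end - truth$start else truth$length <- numeric()
    popmap <- data.frame(sample = sample_ids,
                         breed = sub("_[0-9]+$", "", sample_ids),
                         group = sub("_[0-9]+$", "", sample_ids),
                         stringsAsFactors = FALSE)
    list(panel = panel, truth = truth, popmap = popmap)
  })
}

#' Plant a causal-site allele-frequency difference between groups
#'
#' Resamples the alleles of the named groups at one site from the given
#' frequencies.  Used to create a breed-differentiated causal variant for the
#' F2 association fixture (as in an ear-morphology QTL fixed for alternative
#' alleles in the two founder breeds).
#'
#' @param panel a [haplotype_panel()].
#' @param popmap popmap data.frame.
#' @param site_idx site row index.
#' @param freq_by_group named numeric vector: target alternate-allele
#'   frequency per group.
#' @param seed integer seed.
#' @return the modified panel.
#' @export
plant_causal_site <- function(panel, popmap, site_idx, freq_by_group, seed = 1L) {
  withr::with_seed(seed, {
    for (g in names(freq_by_group)) {
      haps <- group_haplotypes(panel, popmap, g)
      panel$alleles[site_idx, haps] <-
        stats::rbinom(length(haps), 1L, freq_by_group[[g]])
    }
  })
  panel
}

gamete <- function(h1, h2, pos, len, recomb_rate) {
  n_x <- stats::rpois(1, recomb_rate * len)
  cur <- sample(1:2, 1)
  if (n_x == 0) return(if (cur == 1) h1 else h2)
  xpos <- sort(stats::runif(n_x, 0, len))
  phase <- cur + findInterval(pos, xpos)  # switches at each crossover
  ifelse(phase %% 2 == 1, h1, h2)
}

#' Simulate an F2 intercross with a single causal variant
#'
#' F1 individuals are produced by crossing random samples of the two founder
#' populations; F2 individuals by crossing two distinct F1 parents, with
#' Poisson crossovers at `recomb_rate` per bp per meiosis.  The phenotype is
#' `intercept + beta * genotype(causal) + polygenic + noise`, where the
#' polygenic term sums small effects over 200 random markers with variance
#' `polygenic_ratio` times the causal variance (or 1 if `beta = 0`), and the
#' noise variance is set so that the genetic fraction of the phenotypic
#' variance equals `h2`.
#'
#' @param panel founder [haplotype_panel()] (single contig per cross).
#' @param popmap popmap covering the founder samples.
#' @param founders character(2): the two founder population groups.
#' @param causal_site site row index of the causal variant.
#' @param beta causal effect size per alternate-allele copy.
#' @param h2 target heritability in (0, 1).
#' @param n_f2 number of F2 individuals.
#' @param seed integer seed.
#' @param recomb_rate per bp per generation (default 1e-8).
#' @param n_f1 size of the intermediate F1 pool (default 50).
#' @param polygenic_ratio polygenic-to-causal variance ratio (default 1; 0
#'   gives a purely monogenic trait).
#' @return list with `genotypes` (a `genotype_table`: matrix `G` of 0/1/2
#'   dosages, samples x SNPs; `map` with snp/contig/pos; `samples`),
#'   `phenotype` (data.frame `sample`, `trait`) and `causal_site`.
#' @export
simulate_f2_cross <- function(panel, popmap, founders, causal_site, beta, h2,
                              n_f2, seed = 1L, recomb_rate = 1e-8, n_f1 = 50L,
                              polygenic_ratio = 1) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (length(founders) != 2) stop("exactly two founder populations required")
  withr::with_seed(seed, {
    ctg <- panel$contigs$contig[1]
    len <- panel$contigs$length[1]
    pos <- panel$sites$pos
    hapcols <- function(s) paste0(s, c("_h1", "_h2"))
    f_samples <- lapply(founders, function(g) popmap$sample[popmap$group == g])
    if (any(lengths(f_samples) == 0)) stop("founder population absent from panel")
    make_gamete_from_sample <- function(s) {
      hc <- hapcols(s)
      gamete(panel$alleles[, hc[1]], panel$alleles[, hc[2]], pos, len, recomb_rate)
    }
    f1 <- lapply(seq_len(n_f1), function(i) {
      s1 <- sample(f_samples[[1]], 1); s2 <- sample(f_samples[[2]], 1)
      cbind(make_gamete_from_sample(s1), make_gamete_from_sample(s2))
    })
    G <- matrix(0L, n_f2, nrow(panel$sites))
    for (i in seq_len(n_f2)) {
      par <- sample.int(n_f1, 2, replace = FALSE)
      g1 <- gamete(f1[[par[1]]][, 1], f1[[par[1]]][, 2], pos, len, recomb_rate)
      g2 <- gamete(f1[[par[2]]][, 1], f1[[par[2]]][, 2], pos, len, recomb_rate)
      G[i, ] <- g1 + g2
    }
    samples <- sprintf("F2_%03d", seq_len(n_f2))
    rownames(G) <- samples
    map <- data.frame(snp = sprintf("s%05d", seq_len(ncol(G))),
                      contig = ctg, pos = pos, stringsAsFactors = FALSE)
    colnames(G) <- map$snp
    g_c <- G[, causal_site]
    genetic_main <- beta * g_c
    var_c <- stats::var(genetic_main)
    m_poly <- min(200L, ncol(G))
    poly_idx <- sample(setdiff(seq_len(ncol(G)), causal_site), m_poly)
    u_raw <- as.vector(G[, poly_idx, drop = FALSE] %*%
                         stats::rnorm(m_poly, 0, 1))
    var_u_target <- polygenic_ratio * (if (var_c > 0) var_c else 1)
    u <- if (stats::var(u_raw) > 0 && var_u_target > 0)
      u_raw * sqrt(var_u_target / stats::var(u_raw)) else 0 * u_raw
    var_g <- var_c + var_u_target
    var_e <- var_g * (1 - h2) / h2
    y <- 10 + genetic_main + u + stats::rnorm(n_f2, 0, sqrt(var_e))
    list(genotypes = structure(list(G = G, map = map, samples = samples),
                               class = "genotype_table"),
         phenotype = data.frame(sample = samples, trait = y,
                                stringsAsFactors = FALSE),
         causal_site = causal_site)
  })
}

#' Write the complete synthetic fixture suite
#'
#' Writes, deterministically for a given seed: the introgression panel as a
#' phased VCF, its popmap TSV, the ground-truth tract BED, the simulation
#' configuration as YAML, and an F2 genotype/phenotype pair (TSV) with a
#' planted causal site.  Identical seeds yield byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, a named character vector of the written paths.
#' @export
generate_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config_introgression(seed)
  sim <- simulate_panel(cfg)
  paths <- c(
    vcf = file.path(outdir, "panel.vcf"),
    popmap = file.path(outdir, "popmap.tsv"),
    truth = file.path(outdir, "truth_tracts.bed"),
    config = file.path(outdir, "config.yaml"),
    f2_genotypes = file.path(outdir, "f2_genotypes.tsv"),
    phenotype = file.path(outdir, "phenotype.tsv"))
  write_phased_vcf(sim$panel, paths["vcf"])
  write_popmap(sim$popmap, paths["popmap"])
  write_tracts_bed(sim$truth, paths["truth"])
  cfg_list <- list(contig_length = cfg$contig_length, n_contigs = cfg$n_contigs,
                   mutation_density = cfg$mutation_density,
                   gen_time = cfg$gen_time, recomb_rate = cfg$recomb_rate,
                   drift_rate = cfg$drift_rate, seed = cfg$seed,
                   pulses = cfg$pulses,
                   pop_tree = lapply(seq_len(nrow(cfg$pop_tree)), function(i)
                     as.list(cfg$pop_tree[i, ])),
                   n_haplotypes_per_pop = as.list(cfg$n_haplotypes_per_pop))
  yaml::write_yaml(cfg_list, paths["config"])
  cfg2 <- sim_config_f2(seed)
  sim2 <- simulate_panel(cfg2)
  causal <- select_causal_site(sim2$panel)
  sim2$panel <- plant_causal_site(sim2$panel, sim2$popmap, causal,
                                  c(friesian = 0.9, hu = 0.1), seed = seed)
  f2 <- simulate_f2_cross(sim2$panel, sim2$popmap, c("friesian", "hu"),
                          causal, beta = 0.8, h2 = 0.4, n_f2 = 300, seed = seed)
  gdf <- data.frame(sample = f2$genotypes$samples, f2$genotypes$G,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gdf, paths["f2_genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(f2$phenotype, paths["phenotype"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Pick a central well-behaved causal site for the F2 fixture
#'
#' Chooses the site nearest the contig midpoint, so that flanking markers
#' exist on both sides for localization checks.
#' @param panel a [haplotype_panel()].
#' @return site row index.
#' @export
select_causal_site <- function(panel) {
  mid <- panel$contigs$length[1] / 2
  which.min(abs(panel$sites$pos - mid))
}
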