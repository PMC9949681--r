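---
title: "ovintro: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ovintro: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovintro)
```

`ovintro` detects haplotypes introgressed from wild *Ovis* species into
domestic sheep and characterizes their population distribution and phenotypic
associations. This vignette documents the statistical models, the tunable
parameters and the choices made where the design was genuinely open. All
empirical claims made here are the ones the test suite itself computes.

## 1. The synthetic study system

Real analyses of this kind run on hundreds of resequenced genomes; to make
every stage testable against exact ground truth, the package ships a
generator (`simulate_panel()`) whose defaults define the study conditions
used throughout the tests.

**Population tree and drift.** `sim_pop_tree_default()` encodes one outgroup
(6.0 Ma), two wild donors at the divergence times used by the ILS filter
(argali 2.36 Ma, urial 1.26 Ma), a non-introgressed domestic reference group
and four recipient meta-populations radiating at domestication (11 ka).
Per-site ancestral derived-allele frequencies are drawn from Beta(0.5, 3) and
evolve along each branch by a Normal perturbation on the logit scale with
variance `drift_rate * branch_length_years`. This is a deliberately cheap
stand-in for a coalescent: it preserves the tree-structured covariance of
allele frequencies that F_ST, d_XY, D and f_d respond to, but it generates no
within-population linkage disequilibrium and no coalescent variance in local
genealogies. Children of a node branch independently from the node's own
founding frequencies, so sister populations share drift only through their
listed internal ancestors — trees should therefore spell out internal nodes
(as the default tree does). `drift_rate` defaults to 3e-6 per year, which
makes the deep donors strongly differentiated from the domestic lineage (as
wild sheep are) while keeping the 11-ka meta-populations weakly
differentiated.

**Marker density.** `mutation_density` defaults to 3e-3 segregating sites
per bp — a scaled-down emulation of whole-genome-sequencing density (real
data of this kind carries roughly an order of magnitude more). Local
ancestry inference is marker-limited: at much sparser densities short donor
tracts carry too few informative sites to be recovered reliably, which would
say more about the fixture than about the method.

**Admixture pulses.** A pulse `(donor, recipient, admix_time, alpha)` makes
every recipient haplotype an independent two-state Markov mosaic along the
chromosome: donor segments have exponential length with rate
`(1 - alpha) * r * t` and recipient gaps rate `alpha * r * t` (`t` =
admixture age in generations), so the stationary donor fraction is exactly
`alpha` and the expected donor tract length is the classical `1/(r t)` up to
a factor `1/(1 - alpha)`. The commonly quoted Poisson-starts model (tract
starts at rate `alpha r t`, lengths `Exp(1/(r t))`) is its small-`alpha`
limit, but breaks down as `alpha` grows — its stationary coverage is
`1 - exp(-alpha)`, so complete replacement (`alpha = 1`) would cover only
63% of the genome; the Markov form behaves correctly over the whole range
and is what the generator implements. Donor segment alleles are copied from
one randomly chosen donor haplotype per segment, and segments are recorded
verbatim as truth tracts, so ground truth is exact. Tract placement is
independent across haplotypes — real introgressed haplotypes at one locus
share ancestry and therefore share boundaries; consequences for the outlier
stage are discussed in section 5.

**F2 cross.** `simulate_f2_cross()` builds F1 individuals from two founder
breeds (default fixture: two breeds split 10 ka on a 2-Mb contig) and F2
individuals from F1×F1 matings with Poisson crossovers at `r` per bp per
meiosis. The phenotype is
`10 + beta * g_causal + polygenic + noise`, with a polygenic term summing
200 random-marker effects scaled to `polygenic_ratio` times the causal
variance and the noise variance set so that the genetic share of the
phenotypic variance equals `h2`. Because two generations of recombination
barely break a 2-Mb segment, localization power comes from planting a
breed-differentiated causal variant (`plant_causal_site()`, founder
frequencies 0.9/0.1), mimicking a QTL fixed for alternative alleles in the
founder breeds — the design situation of an ear-morphology F2 study. Study
condition for the power checks: `beta = 0.8`, `h2 = 0.4`, `n_f2 = 300`.

**What passing tests do and do not show.** Tests on these fixtures validate
the estimators' algebra, their calibration under the null, and parameter
recovery when the generative model matches the assumptions (tree-structured
drift, exponential tracts, site-independent haplotypes). They do not probe
robustness to phasing error, genotype error, background LD, selection, or
coalescent noise in local genealogies — on real data all thresholds below
deserve sensitivity analysis.

## 2. Local ancestry inference

`copy_path_dp()` minimizes `n_mismatches + lambda * n_switches` over all
assignments of one reference template per site (Viterbi-style DP,
O(sites × templates)). Ties are broken toward fewer switches, then the lowest
template index, making output deterministic. Missing alleles incur no
mismatch. The non-introgressed domestic reference group must always be among
the sources so "no donor" is expressible.

**Switch penalty `lambda`** (mismatch-equivalents per ancestry switch,
default **5**). The penalty trades false donor segments against boundary
precision, and no external value fits all marker densities. We chose the
default by a sensitivity grid on the default fixtures: at small penalties
(around 1.5) spurious short donor segments inflate the no-admixture false
positive rate well above the 2% bound the test suite enforces, while very
large penalties slowly erode base-pair precision on true tracts; 5 satisfies
both the <2% null bound and the >=0.90 precision/recall targets with margin.
The monotonicity of switch count in `lambda` is a tested invariant, so users
can rerun the scan over a `lambda` grid cheaply for their own data.

**Tract boundaries** are placed at the midpoint between the last site of one
source run and the first site of the next — unbiased on average; with dense
markers the induced error is small relative to the >=50-kb tracts of
interest. Each haplotype's tracts partition `[0, contig_length)`.

**Bagging** (off by default; `bagging_reps = 20`, `bag_frac = 0.8` is a
reasonable setting) repeats the DP on random template subsets and takes a
per-site majority vote, ties resolved to the recipient reference — a
conservative stabilizer for small reference panels. One repetition is
defined to be the plain DP.

## 3. ILS expected length and tract filtering

Two lineages that diverged `t` years ago accumulate recombination on both
branches, so a shared ancestral tract has expected surviving length
`L = 1/(r T)` with `T = 2 t / g` generations (`g` = generation time, 4
years). With `r = 1e-8` this gives 159 bp (urial, 1.26 Ma), 85 bp (argali,
2.36 Ma) and 64 bp (bighorn/thinhorn, 3.12 Ma). The mouflon case is too
recent for this filter to matter at these scales: 0.032 Ma gives 6,250 bp
from the same formula (published analyses quote a slightly different rounded
value, suggesting a slightly different divergence input; we do not force
agreement). Tract length under ILS is the sum of two exponential arms,
Gamma(shape 2, rate 1/L), so `ils_survival_prob(m, L) = (1 + m/L) e^{-m/L}`;
the closed form is tested against `pgamma` to 1e-12. `filter_tracts_by_L()`
removes tracts strictly shorter than `L` for their source (a tract of
exactly `L` survives), and can recompute `L` per tract from a local
recombination map; gaps in the map fall back to the genome-wide default
rate.

## 4. Window statistics

All statistics run on the 50-kb/20-kb sliding grid (`iterate_windows()`);
terminal clipped windows are kept and flagged, and each statistic is
normalized by the true window length. A window needs `min_sites = 10` usable
sites (default) — small enough to retain most windows at fixture density,
large enough to avoid unstable ratios; it is a config knob, not a claim.

- **F_ST**: Weir–Cockerham (1984) on diploid genotypes reconstructed from
  the phased haplotype pairs, combined across sites as a ratio of sums —
  matching the windowed estimator of the standard VCF tooling. Sites where
  either group has fewer than 2 complete genotypes are excluded. The Hudson
  estimator is available (`estimator = "hudson"`) for sensitivity analysis.
- **d_XY**: `(1/L_win) * sum pA(1-pB) + pB(1-pA)`; invariant sites add 0, so
  only segregating sites need enumeration.
- **D and f_d**: frequency-weighted ABBA/BABA with the derived allele
  polarized by the outgroup consensus: sites with outgroup frequency in
  (0.1, 0.9) are excluded, and frequencies are flipped where the outgroup
  frequency exceeds 0.5. `f_d` uses the dynamic donor (the per-site larger
  of P2/P3 frequencies) in the denominator and is reported `NA` where the
  window's D is negative or the denominator non-positive (the estimator is
  meaningful only for an excess of shared derived alleles); such windows are
  excluded from the Z-scan.
- **Z tests**: two-tailed for f_d, upper-tailed for F_ST (a selection scan
  looks for significantly *high* differentiation); both flag windows at
  `P < 0.001`. A constant statistic yields a warning and all `P = 1`.
- **Permutation threshold**: per replicate, draw 33 domestic samples
  (default), pool with the wild group, split at random into two equal
  pseudo-populations, take the genome-wide maximum windowed F_ST; the
  threshold is the largest maximum over 100 replicates (defaults; the tests
  scale reps down). This threshold reflects pure sampling noise plus pool
  heterogeneity, and on the introgression fixture it sits far below the top
  percentile of the real domestic-vs-donor scan.

## 5. Tract frequencies and outlier selection

`tract_frequency()` scores, for each candidate interval, which recipient
haplotypes "carry" it: same-source inferred ancestry must cover at least
`coverage_frac = 0.8` of the interval — a definition this package fixes
explicitly because published analyses rarely state one; 0.8 tolerates
boundary noise while excluding half-covered haplotypes. Frequencies are
reported per meta-population (SD and range computed with equal weight per
meta-population) and pooled over all recipient haplotypes ("total
frequency"). Outliers are kept at length >= 100 kb, total frequency >= 0.05
and SD > 0.1. Default candidates are the distinct inferred donor tracts
themselves; because the generator places tracts independently across
haplotypes, tract boundaries do not coincide across carriers as they would
in real data, so the tests also evaluate explicit truth intervals as
candidates. High-F_ST regions merge significant windows separated by at most
50 kb; outlier tracts are annotated with the regions they overlap (>= 1 bp).

## 6. Haplotype structure of candidate regions

`extract_region()` removes sites with MAF <= 0.05 (boundary removed, per the
convention of haplotype-pattern analyses). Recombinant screening — a rule
this package defines explicitly, since published pipelines describe it only
loosely — seeds consensus strings from the `k_major = 3` largest identical
haplotype classes, keeps outright any haplotype within `max_diff_frac = 0.1`
of a consensus, and flags a haplotype whose best two-segment chimera of two
consensus strings beats its best single consensus by at least 5 mismatches.
Haplogroups are single-linkage clusters cut at Hamming distance
`0.05 * n_sites`, labelled `hap-1, hap-2, ...` by decreasing size; frequency
tables report exact fractions alongside round-half-even 3-decimal
frequencies (155/1831 prints as 0.085, 63/68 as 0.926), so either printing
convention is recoverable. Networks collapse identical haplotypes into
multiplicity-weighted nodes and build a minimum spanning tree on pairwise
Hamming distances (pairwise-complete over missing sites) with Prim's
algorithm and a deterministic tie-break (weight, then node order);
alternative edges — non-tree edges no heavier than the heaviest edge on the
tree path between their endpoints — are reported for network ambiguity.

## 7. Linear mixed model association

`lmm_scan()` fits `y = Wα + xβ + u + ε`, `u ~ MVN(0, λτ⁻¹K)`,
`ε ~ MVN(0, τ⁻¹Iₙ)`, with `K` the centered genotype cross-product over SNPs
(`kinship_matrix()`; mean imputation of missing genotypes, zero-variance
SNPs excluded). `λ` is estimated once by maximum likelihood on the null
model — a log10 grid from 1e-5 to 1e5 in 0.25 steps, refined by
golden-section search to 1e-6 — using the eigendecomposition of `K`, then
held fixed across SNPs (the standard scan approximation). Each SNP is tested
by GLS in the rotated space with a Wald χ²(1) statistic. With `K = I` the
scan reduces exactly to OLS (tested to 1e-8), and P values are invariant to
affine rescaling of the trait. QC removes samples above 10% missingness
first, then SNPs below MAF 0.05 or above 10% missingness; the F2 fixture is
complete, so imputation-quality filters are out of scope here. Covariates
default to the intercept only (the fixture phenotype has no simulated
covariate structure; `W` accepts any design matrix).

One calibration note: the permuted-trait uniformity check in the test suite
draws its 1000 null P values from 100 independent trait permutations × 10
SNPs each, rather than from a single scan, because the Kolmogorov–Smirnov
test assumes independent draws and F2 family structure correlates genotype
columns across the whole chromosome.

## 8. Problem sizes and determinism

The test fixtures use 3-Mb (single-contig) panels at 3e-3 sites/bp with
about 150 haplotypes, a 2 × 5-Mb panel for window-level null calibration,
and 100 seeded replicates for the LMM power and effect-recovery checks —
sizes chosen so the full suite exercises every stage at meaningful
Monte-Carlo resolution while remaining a desk-scale computation. All
randomness flows through explicit integer seeds (`withr::with_seed`); no
function leaves the global RNG in a changed state, and
`generate_fixture_suite()` writes byte-identical files for identical seeds.
Coordinates are 0-based half-open everywhere inside the package and
converted to 1-based only in VCF output and human-readable tables.

## 9. Known limitations

- The drift generator produces no within-population LD, no mutation
  recurrence, and no coalescent variance; calibration results transfer to
  real data only approximately.
- The LAI model ignores phasing error and does not jointly model diploids;
  `lambda` should be treated as a data-dependent tuning parameter.
- Genome-wide D is reported per window without block-jackknife standard
  errors (window Z-scores serve as the scan-level significance device).
- Gene annotation of outlier regions, phylogenetic trees, and
  median-joining networks are outside the package's scope.
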