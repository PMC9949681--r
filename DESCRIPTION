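Package: ovintro
Title: Detection and Characterization of Wild-Sheep Introgression in Domestic Sheep Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting and characterizing haplotypes introgressed
    from wild Ovis species into domestic sheep from phased biallelic genotypes.
    Provides local-ancestry inference by minimal-cost haplotype copying,
    windowed introgression and differentiation statistics (Weir-Cockerham and
    Hudson F_ST, d_XY, Patterson's D and the f_d admixture-fraction estimator)
    with Z-test and permutation significance thresholds, an incomplete-lineage-
    sorting tract-length filter based on the Gamma survival function of shared
    ancestral tract lengths, outlier-tract selection by frequency variation
    across meta-populations, haplogroup clustering and minimum-spanning-tree
    haplotype networks, and a kinship linear-mixed-model association scan for
    F2-cross phenotypes. A synthetic-data module generates phased panels with
    known introgression tracts and an F2 genotype/phenotype set so that every
    stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
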