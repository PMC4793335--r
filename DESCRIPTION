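Package: stagemix
Title: Life-Stage Sampling, Sibship, and Isolation-by-Distance Inference for
    Pond-Breeding Amphibians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how sampling different amphibian life stages
    (adults, embryos, larvae), retaining full siblings, and varying the number
    of microsatellite loci affect population-genetic summaries and
    isolation-by-distance inference. Provides diploid microsatellite genotype
    containers with GENEPOP and CSV readers/writers, a pedigree-aware
    synthetic-data generator emulating a multi-pond study design with
    clutch-structured juvenile cohorts, Hardy-Weinberg locus screening and
    sibling pruning, observed heterozygosity, rarefied allelic richness,
    Weir-Cockerham F_ST, Cavalli-Sforza/Edwards chord distance, a
    linkage-disequilibrium effective-population-size estimator, permutation and
    exact Mantel tests, mixed-tissue bootstrap resampling, a juvenile-proportion
    by locus-count mixture grid, and permutation/bootstrap group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
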