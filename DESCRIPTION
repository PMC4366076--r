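Package: gwaspath
Title: Gene-Based Association Mapping and Pathway Enrichment for Metabolic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based genome-wide association mapping with the sum of
    squared score (SSU) test and a cumulant-matched chi-square approximation
    for its quadratic-form null distribution, population-stratification
    correction via genotype principal components selected by the Tracy-Widom
    test, Bonferroni and Benjamini-Hochberg multiple-testing control, and
    permutation-based gene-set enrichment of the resulting gene ranking
    (weighted Kolmogorov-Smirnov enrichment score and Wilcoxon rank-sum
    statistic).  Includes a synthetic cohort generator (Balding-Nichols
    population divergence, latent AR(1) linkage disequilibrium, a linear
    phenotype model with planted causal genes and a causal pathway) so the
    full pipeline is testable at desk scale, plus readers and writers for
    PED/MAP, dosage TSV, BED gene annotation and GMT pathway files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
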