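#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# The generator emulates the design of the dairy-cow study the pipeline is
# built for: 244 genotyped animals in two breed groups (178 + 66) with
# allele-frequency divergence between them, gene-sized LD blocks, three
# metabolite-like traits measured at T1/T2/T3, one planted causal gene and
# one causal pathway carrying it.  Everything is written as plain text so
# stages 2-4 run from files, as they would on real data.

library(gwaspath)

out_dir <- "results/cohort"

sim <- sim_config(
  n_samples = 244, group_sizes = c(178, 66), fst = 0.1,
  n_genes = 120, snps_per_gene = c(10, 25), intergenic_snps = 100,
  ld_rho = 0.5, n_pathways = 12, genes_per_pathway = c(10, 10),
  traits = c("nefa", "bhba", "glucose"),
  causal_genes = data.frame(gene = 42, n_snps = 8, beta = 0.25),
  causal_pathway_index = 3,
  study_fraction = 0.8, covariate_effects = c(group = 0.3, study = 0.2),
  seed = 20260923
)

cohort <- simulate_cohort(sim)
paths <- write_cohort(cohort, out_dir)

cat("cohort written to", out_dir, "\n")
print(cohort$genotypes)
cat("genes annotated:", nrow(cohort$genes),
    "| pathways:", length(cohort$pathways), "\n")
cat("planted causal gene:", cohort$truth$causal_genes,
    "in", cohort$truth$causal_pathway,
    sprintf("(heritable fraction at T2: %.2f)\n", cohort$truth$h2_t2))
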