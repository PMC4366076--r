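#!/usr/bin/env Rscript
# Stage 2: quality control and population structure.
#
# Reads the cohort written by stage 1, applies the call-rate/MAF filter
# with mode imputation, runs the genotype PCA within the larger breed
# group, selects significant components with the Tracy-Widom test and
# assembles the covariate matrix used by the association stages.

library(gwaspath)

geno <- read_genotypes("results/cohort/genotypes", "ped_map")
pheno <- read_phenotypes("results/cohort/phenotypes.tsv")
geno$samples$group <- pheno$group[match(geno$samples$sample_id,
                                        pheno$sample_id)]

geno_qc <- qc_filter(geno, min_call_rate = 0.95, min_maf = 0.05)
rep <- attr(geno_qc, "qc_report")
cat(sprintf("QC: %d SNPs in, %d removed by call rate, %d by MAF, %d kept\n",
            rep$n_input, rep$removed_call_rate, rep$removed_maf,
            rep$n_kept))

in_g1 <- geno_qc$samples$group == 1
pca <- genotype_pca(geno_qc, geno_qc$samples$sample_id[in_g1])
n_comp <- tracy_widom_count(pca, alpha = 0.01)
cat("Tracy-Widom significant components (alpha = 0.01):", n_comp, "\n")
cat(sprintf("PC1 explains %.1f%% of the standardized variance\n",
            100 * pca$var_frac[1]))

Z <- build_covariate_matrix(geno_qc$samples$sample_id, in_g1, pca, n_comp)
cat("covariate matrix:", ncol(Z), "columns:",
    paste(colnames(Z), collapse = ", "), "\n")

dir.create("results/structure", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(component = seq_along(pca$eigenvalues),
                       eigenvalue = pca$eigenvalues,
                       var_frac = pca$var_frac),
            "results/structure/eigenvalues.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = pca$sample_ids,
                       pca$scores[, 1:min(10, ncol(pca$scores))]),
            "results/structure/pc_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = geno_qc$samples$sample_id, Z,
                       check.names = FALSE),
            "results/structure/covariates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("structure tables written to results/structure\n")
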