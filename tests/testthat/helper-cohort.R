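# shared fixture builders: everything is generated in code at test time

# simulate + QC + map + PCA + covariates in one step
prep_cohort <- function(cfg, n_components = "auto") {
  co <- simulate_cohort(cfg)
  geno <- qc_filter(co$genotypes)
  gm <- map_snps_to_genes(geno, co$genes)
  in_g1 <- geno$samples$group == 1
  pca <- genotype_pca(geno, geno$samples$sample_id[in_g1])
  nc <- if (identical(n_components, "auto")) tracy_widom_count(pca)
        else n_components
  Z <- build_covariate_matrix(geno$samples$sample_id, in_g1, pca, nc)
  list(cohort = co, geno = geno, gene_map = gm, pca = pca, Z = Z,
       n_components = nc)
}

# 3-sample, 2-SNP PED/MAP text fixture: SNP1 genotypes AA / AB / BB,
# SNP2 has one missing genotype
write_tiny_ped <- function(dir) {
  writeLines(c(
    "F1 S1 0 0 0 -9 A A C C",
    "F2 S2 0 0 0 -9 A B 0 0",
    "F3 S3 0 0 0 -9 B B C G"
  ), file.path(dir, "tiny.ped"))
  writeLines(c(
    "1\trs1\t0\t1000",
    "1\trs2\t0\t2000"
  ), file.path(dir, "tiny.map"))
  file.path(dir, "tiny")
}
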