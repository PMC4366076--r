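test_that("PED/MAP parsing codes dosage as minor-allele counts", {
  dir <- withr::local_tempdir()
  g <- read_genotypes(write_tiny_ped(dir), "ped_map")
  # rs1: AA/AB/BB -> B is minor-or-tied, counted: 0,1,2
  expect_equal(unname(g$dosage[, "rs1"]), c(0, 1, 2))
  # rs2: CC/missing/CG -> G minor: 0,NA,1
  expect_equal(unname(g$dosage[, "rs2"]), c(0, NA, 1))
  expect_equal(unname(g$snps$call_rate), c(1, 2 / 3))
  expect_equal(g$snps$pos, c(1000, 2000))
  expect_equal(g$samples$sample_id, c("S1", "S2", "S3"))
})

test_that("PED parser rejects malformed input by line", {
  dir <- withr::local_tempdir()
  prefix <- write_tiny_ped(dir)
  lines <- readLines(paste0(prefix, ".ped"))
  writeLines(c(lines, "F4 S4 0 0 0 -9 A A"), paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, "ped_map"), "line 4")
  writeLines(c(lines[1:2], "F3 S3 0 0 0 -9 T T C G"), paste0(prefix, ".ped"))
  expect_error(read_genotypes(prefix, "ped_map"), "not biallelic")
})

test_that("PED/MAP and dosage TSV round-trip a simulated cohort", {
  cfg <- sim_config(n_samples = 40, n_genes = 8, snps_per_gene = c(4, 8),
                    n_pathways = 2, genes_per_pathway = c(5, 5), seed = 31)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ped <- read_genotypes(file.path(dir, "genotypes"), "ped_map")
  tsv <- read_genotypes(file.path(dir, "dosage.tsv"), "tsv_dosage")
  expect_equal(unname(ped$dosage), unname(co$genotypes$dosage))
  expect_equal(unname(tsv$dosage), unname(co$genotypes$dosage))
  expect_equal(ped$snps$snp_id, co$genotypes$snps$snp_id)
  expect_equal(ped$snps$pos, co$genotypes$snps$pos)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph$sample_id, co$phenotypes$sample_id)
  expect_equal(ph$nefa_T2, co$phenotypes$nefa_T2, tolerance = 1e-9)
  genes <- read_gene_bed(file.path(dir, "genes.bed"))
  expect_equal(genes$start, co$genes$start)
  expect_equal(genes$end, co$genes$end)
  pw <- read_pathways(file.path(dir, "pathways.gmt"), genes = genes)
  expect_equal(pw[order(names(pw))],
               co$pathways[order(names(co$pathways))],
               ignore_attr = TRUE)
  expect_length(readLines(file.path(dir, "pathways.gmt")), 2)
})

test_that("QC thresholds are inclusive and imputation fills the mode", {
  # 20 samples; construct SNPs at known call rate / MAF
  dos <- cbind(
    maf04 = c(rep(1, 4), rep(0, 46)),        # maf 0.04
    maf05 = c(rep(1, 5), rep(0, 45)),        # maf 0.05 exactly
    cr094 = c(NA, NA, NA, rep(2, 44), 1, 1, 0),
    cr095 = c(rep(NA, 2), NA, rep(1, 27), rep(0, 20)),
    good = c(rep(0, 20), rep(1, 20), rep(2, 10))
  )
  # fix call rates: cr094 -> 47/50 = 0.94, cr095 needs 0.95 not 0.94
  dos[, "cr095"] <- c(NA, NA, rep(1, 28), rep(0, 20))  # 48/50 = 0.96
  snps <- data.frame(snp_id = colnames(dos), chrom = "1", pos = 1:5 * 100)
  g <- genotype_matrix(dos, snps,
                       data.frame(sample_id = sprintf("S%02d", 1:50)))
  expect_equal(unname(g$snps$call_rate[3]), 0.94)
  out <- qc_filter(g, min_call_rate = 0.95, min_maf = 0.05)
  kept <- out$snps$snp_id
  expect_false("maf04" %in% kept)   # below MAF threshold
  expect_true("maf05" %in% kept)    # inclusive boundary
  expect_false("cr094" %in% kept)   # below call-rate threshold
  expect_true("cr095" %in% kept)
  expect_false(anyNA(out$dosage))   # mode imputation
  expect_equal(unname(out$dosage[1:2, "cr095"]), c(1, 1))
  qrep <- attr(out, "qc_report")
  expect_equal(qrep$removed_call_rate, 1)
  expect_equal(qrep$removed_maf, 1)
  expect_warning(qc_filter(g, min_maf = 0.6), "every SNP")
})

test_that("raising the MAF threshold never keeps more SNPs", {
  cfg <- sim_config(n_samples = 80, n_genes = 15, maf_range = c(0.02, 0.5),
                    missing_rate = 0.02, seed = 12)
  g <- simulate_genotypes(cfg)
  counts <- vapply(c(0, 0.05, 0.1, 0.2),
                   function(t) ncol(qc_filter(g, min_maf = t)$dosage),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SNP-to-gene mapping honours the 5 kbp closed boundary", {
  snps <- data.frame(snp_id = c("a", "b", "c", "d", "e"), chrom = "1",
                     pos = c(5000, 4999, 10000, 20000, 25001))
  dos <- matrix(rep(c(0, 1, 2, 1), 5), nrow = 4)
  g <- genotype_matrix(dos, snps, data.frame(sample_id = paste0("S", 1:4)))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                      start = c(10000, 18000), end = c(20000, 19000))
  map <- map_snps_to_genes(g, genes, flank = 5000)
  # start - 5000 = 5000 assigned; 4999 not; end + 5000 = 25000 excludes 25001
  expect_equal(g$snps$snp_id[map$g1], c("a", "c", "d"))
  # SNP inside two overlapping windows belongs to both genes
  expect_true("d" %in% g$snps$snp_id[map$g2])
  # unknown chromosome yields no assignment
  genes2 <- data.frame(gene_id = "g3", chrom = "7", start = 1, end = 1e6)
  expect_length(map_snps_to_genes(g, genes2), 0)
  # brute-force rescan agrees
  for (gi in seq_len(nrow(genes))) {
    manual <- which(snps$chrom == genes$chrom[gi] &
                      snps$pos >= genes$start[gi] - 5000 &
                      snps$pos <= genes$end[gi] + 5000)
    expect_equal(unname(map[[genes$gene_id[gi]]]), manual)
  }
})

test_that("GMT reading filters on post-intersection membership", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "p.gmt")
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20))
  writeLines(c(
    paste(c("pw1", "six listed, four annotated", "g01", "g02", "g03",
            "g04", "x1", "x2"), collapse = "\t"),
    paste(c("pw2", "five annotated", sprintf("g%02d", 5:9)),
          collapse = "\t"),
    paste(c("pw3", "all annotated", sprintf("g%02d", 10:17)),
          collapse = "\t")
  ), gmt)
  pw <- read_pathways(gmt, genes = genes, min_genes = 5)
  expect_named(pw, c("pw2", "pw3"))
  expect_length(pw$pw2, 5)
  # duplicate ids are an error
  writeLines(c("pw1\td\tg01\tg02\tg03\tg04\tg05",
               "pw1\td\tg06\tg07\tg08\tg09\tg10"), gmt)
  expect_error(read_pathways(gmt, genes = genes), "duplicate")
  writeLines(character(), gmt)
  expect_warning(p0 <- read_pathways(gmt, genes = genes), "empty")
  expect_length(p0, 0)
})

test_that("phenotype reading enforces ids and numeric traits", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ph.tsv")
  tab <- data.frame(sample_id = sprintf("S%03d", 1:244), group = 1,
                    met_T1 = rnorm(244), met_T2 = rnorm(244),
                    met_T3 = rnorm(244))
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- read_phenotypes(f)
  expect_equal(nrow(ph), 244)
  expect_equal(sum(stats::complete.cases(ph$met_T1)), 244)
  # a sample missing T1 stays usable for T2/T3
  tab$met_T1[7] <- NA
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- read_phenotypes(f)
  expect_true(is.na(ph$met_T1[7]) && !is.na(ph$met_T2[7]))
  # duplicated id
  tab2 <- tab
  tab2$sample_id[2] <- "S001"
  utils::write.table(tab2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(f), "duplicated sample id")
  # non-numeric cell named by row
  tab3 <- tab
  tab3$met_T2 <- as.character(tab3$met_T2)
  tab3$met_T2[11] <- "oops"
  utils::write.table(tab3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(f), "row 11")
})

test_that("ratio phenotypes follow later/earlier with guarded denominators", {
  tab <- data.frame(sample_id = c("a", "b", "c"),
                    met_T1 = c(1, 0, 2), met_T2 = c(2, 3, 4),
                    met_T3 = c(4, 6, 1))
  expect_warning(out <- compute_ratio_phenotypes(tab), "denominator")
  expect_equal(out$met_T2_T1, c(2, NA, 2))
  expect_equal(out$met_T3_T1, c(4, NA, 0.5))
  expect_equal(out$met_T3_T2, c(2, 2, 0.25))
  # log-scale trait: raw-scale ratio is exp of the difference
  ltab <- data.frame(sample_id = "a", nefa_T1 = 1, nefa_T2 = 3)
  out2 <- compute_ratio_phenotypes(ltab, ratios = "T2_T1",
                                   log_traits = "nefa")
  expect_equal(out2$nefa_T2_T1, exp(2))
  out3 <- compute_ratio_phenotypes(ltab, ratios = "T2_T1",
                                   log_traits = "nefa", log_ratio = TRUE)
  expect_equal(out3$nefa_T2_T1, 2)
})
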