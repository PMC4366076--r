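#' Simulate genotypes for a structured two-group cohort
#'
#' Allele frequencies diverge between groups under the Balding-Nichols
#' model: with ancestral frequency `p` and divergence `fst = F`, each
#' group's frequency is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose
#' mean is `p` and variance `F p (1-p)`.  Within each gene block, linkage
#' disequilibrium is induced by a latent AR(1) Gaussian: each haplotype is
#' a correlated standard-normal vector (`cor(z_i, z_j) = ld_rho^|i-j|`)
#' thresholded at the frequency quantile, and two independent haplotypes
#' are summed per individual.  Intergenic SNPs are drawn independently and
#' placed between the flanked gene intervals so they map to no gene.
#'
#' @param config a [sim_config()] object.
#' @return a [genotype_matrix()]; the SNP table carries a `block` column
#'   (gene index, `NA` for intergenic SNPs) used by [build_annotations()].
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  ngr <- config$n_groups
  grp <- rep(seq_len(ngr), times = config$group_sizes)

  # SNP counts per block: gene blocks first, then singleton intergenic SNPs
  gene_sizes <- draw_range(config$snps_per_gene, config$n_genes)
  blocks <- c(gene_sizes, rep(1L, config$intergenic_snps))
  block_gene <- c(seq_len(config$n_genes), rep(NA_integer_,
                                               config$intergenic_snps))
  m <- sum(blocks)
  if (m == 0) stop("configuration produces zero SNPs")

  # ancestral and per-group frequencies (Balding-Nichols)
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  f <- config$fst
  p_grp <- matrix(0, nrow = ngr, ncol = m)
  for (g in seq_len(ngr)) {
    if (f == 0) {
      p_grp[g, ] <- p_anc
    } else {
      p_grp[g, ] <- stats::rbeta(m, p_anc * (1 - f) / f,
                                 (1 - p_anc) * (1 - f) / f)
    }
  }
  p_grp <- pmin(pmax(p_grp, 1e-4), 1 - 1e-4)

  rho <- config$ld_rho
  dosage <- matrix(0L, nrow = n, ncol = m)
  col0 <- 0L
  for (b in seq_along(blocks)) {
    s <- blocks[b]
    if (s == 0) next
    cols <- col0 + seq_len(s)
    for (g in seq_len(ngr)) {
      rows <- which(grp == g)
      nh <- 2L * length(rows)
      # latent AR(1) Gaussian haplotypes, thresholded at the freq quantile
      z <- matrix(stats::rnorm(nh * s), nrow = nh, ncol = s)
      if (rho > 0 && s > 1) {
        for (j in 2:s) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      thr <- stats::qnorm(p_grp[g, cols])
      hap <- sweep(z, 2, thr, `<`)
      dosage[rows, cols] <- hap[seq_len(length(rows)), , drop = FALSE] +
        hap[length(rows) + seq_len(length(rows)), , drop = FALSE]
    }
    col0 <- col0 + s
  }

  # genomic layout: one chromosome, 500 bp within-block spacing, 20 kbp
  # gaps between blocks so 5 kbp flanks never bridge neighbouring genes;
  # intergenic singletons land in the middle of their own gap
  pos <- integer(m)
  cur <- 1L
  col0 <- 0L
  for (b in seq_along(blocks)) {
    s <- blocks[b]
    if (s > 0) {
      pos[col0 + seq_len(s)] <- cur + 500L * (seq_len(s) - 1L)
      cur <- cur + 500L * (s - 1L) + 20000L
      col0 <- col0 + s
    }
  }
  snp_gene <- rep(block_gene, times = blocks)
  snp_id <- sprintf("snp%05d", seq_len(m))

  # orient every column to count the realized minor allele, so the dosage
  # matrix is the canonical minor-allele coding the readers also produce
  flip <- colMeans(dosage) / 2 > 0.5
  dosage[, flip] <- 2L - dosage[, flip]

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dosage[mask] <- NA_integer_
  }

  study <- if (config$study_fraction > 0) {
    as.integer(stats::runif(n) < config$study_fraction)
  } else rep(0L, n)

  genotype_matrix(
    dosage = dosage,
    snps = data.frame(snp_id = snp_id, chrom = "1", pos = pos,
                      block = snp_gene, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                         group = grp, study = study,
                         stringsAsFactors = FALSE)
  )
}
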