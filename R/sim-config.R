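#' Simulation configuration for a synthetic genotyped cohort
#'
#' Describes a desk-scale cohort with the statistical structure the
#' downstream analysis assumes: two (or more) groups with Balding-Nichols
#' allele-frequency divergence, gene-sized blocks of SNPs in linkage
#' disequilibrium generated from a latent AR(1) Gaussian, continuous
#' phenotypes from the linear model y = Z theta + X beta + epsilon at three
#' time points, and planted causal genes collected in one causal pathway.
#'
#' @param n_samples total number of individuals.
#' @param group_sizes integer vector of per-group sizes; must sum to
#'   `n_samples`.  Default splits roughly 3:1, mirroring a cohort dominated
#'   by one breed group.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`; 0 means the
#'   groups share allele frequencies exactly.
#' @param n_genes number of gene blocks.
#' @param snps_per_gene length-2 integer range; each gene draws its SNP
#'   count uniformly from it.
#' @param intergenic_snps number of isolated SNPs placed between gene
#'   blocks, outside every gene's flanked interval.
#' @param maf_range ancestral minor-allele-frequency interval within
#'   `(0, 0.5]`.
#' @param ld_rho latent AR(1) correlation in `[0, 1)` between adjacent SNPs
#'   of a gene block (0 = linkage equilibrium).
#' @param causal_genes data frame with columns `gene` (1-based gene index),
#'   `n_snps` (causal SNPs planted in that gene) and `beta` (per-SNP effect
#'   in units of `noise_sd`); `NULL` for a fully null cohort.
#' @param causal_pathway_index 1-based index of the pathway that will
#'   contain every causal gene, or `NULL`.
#' @param n_pathways number of gene sets to emit.
#' @param genes_per_pathway length-2 range of pathway sizes; minimum 5,
#'   matching the pathway-annotation filter used downstream.
#' @param traits character vector of trait names; all traits share the
#'   genetic term and differ by independent noise.
#' @param time_multipliers named numeric vector scaling the shared genetic
#'   term at T1/T2/T3; the default concentrates the genetic signal at the
#'   high-metabolic-load time T2.
#' @param baseline named numeric vector of per-time intercepts.  The
#'   defaults sit well above the unit noise scale (as metabolite levels
#'   do) so that raw-scale ratio phenotypes between times are well
#'   behaved.
#' @param noise_sd residual standard deviation of every trait/time.
#' @param covariate_effects named numeric vector: `group` is the additive
#'   shift for members of group 1, `study` the shift for the (optional)
#'   study/management indicator.
#' @param study_fraction fraction of samples flagged as coming from the
#'   first (on-farm-like) study; drawn independently of group.
#' @param missing_rate per-entry probability of a missing genotype; 0 by
#'   default, non-zero only to exercise QC and mode imputation.
#' @param seed integer seed making the whole cohort reproducible.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 244,
                       group_sizes = NULL,
                       fst = 0.1,
                       n_genes = 100,
                       snps_per_gene = c(5, 25),
                       intergenic_snps = 0,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.5,
                       causal_genes = NULL,
                       causal_pathway_index = NULL,
                       n_pathways = 10,
                       genes_per_pathway = c(5, 15),
                       traits = "nefa",
                       time_multipliers = c(T1 = 0.5, T2 = 1, T3 = 0.5),
                       baseline = c(T1 = 4.3, T2 = 5.6, T3 = 4.6),
                       noise_sd = 1,
                       covariate_effects = c(group = 0, study = 0),
                       study_fraction = 0,
                       missing_rate = 0,
                       seed = 1L) {
  if (is.null(group_sizes)) {
    g1 <- round(n_samples * 0.73)
    group_sizes <- c(g1, n_samples - g1)
  }
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_groups = length(group_sizes),
    group_sizes = as.integer(group_sizes),
    fst = fst,
    n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    intergenic_snps = as.integer(intergenic_snps),
    maf_range = maf_range,
    ld_rho = ld_rho,
    causal_genes = causal_genes,
    causal_pathway_index = causal_pathway_index,
    n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway),
    traits = traits,
    time_multipliers = time_multipliers,
    baseline = baseline,
    noise_sd = noise_sd,
    covariate_effects = covariate_effects,
    study_fraction = study_fraction,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 2) stop("n_samples must be at least 2")
  if (sum(cfg$group_sizes) != cfg$n_samples)
    stop("group_sizes must sum to n_samples")
  if (any(cfg$group_sizes < 1)) stop("group sizes must be positive")
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must lie in [0, 1)")
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (length(cfg$snps_per_gene) != 2 || any(cfg$snps_per_gene < 0) ||
      cfg$snps_per_gene[2] < 1 ||
      cfg$snps_per_gene[1] > cfg$snps_per_gene[2])
    stop("snps_per_gene must be a non-decreasing range with positive maximum")
  if (cfg$intergenic_snps < 0) stop("intergenic_snps must be non-negative")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!is.null(cfg$causal_genes)) {
    cg <- cfg$causal_genes
    if (!all(c("gene", "n_snps", "beta") %in% names(cg)))
      stop("causal_genes needs columns gene, n_snps, beta")
    if (any(cg$gene < 1 | cg$gene > cfg$n_genes))
      stop("causal gene index out of range")
    if (any(cg$n_snps < 1))
      stop("each causal gene needs at least one causal SNP")
  }
  if (cfg$n_pathways > 0) {
    if (length(cfg$genes_per_pathway) != 2 || cfg$genes_per_pathway[1] < 5 ||
        cfg$genes_per_pathway[1] > cfg$genes_per_pathway[2])
      stop("genes_per_pathway must be a range with minimum at least 5")
    if (!is.null(cfg$causal_pathway_index) &&
        (cfg$causal_pathway_index < 1 ||
         cfg$causal_pathway_index > cfg$n_pathways))
      stop("causal_pathway_index out of range")
  }
  if (!setequal(names(cfg$time_multipliers), c("T1", "T2", "T3")))
    stop("time_multipliers must be named T1, T2, T3")
  invisible(cfg)
}
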