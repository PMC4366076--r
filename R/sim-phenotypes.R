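#' Simulate phenotypes from the linear model y = Z theta + X beta + epsilon
#'
#' Each trait is generated at the three sampling times T1/T2/T3.  All
#' traits and times share one genetic term `g = X_causal beta` (causal
#' SNPs are evenly spaced within their gene block; `beta` is expressed in
#' units of `noise_sd`), scaled per time by `time_multipliers`, so ratio
#' phenotypes between times remain sensitive to the planted genetics.
#' Nuisance structure enters through the group and study indicators with
#' coefficients `covariate_effects`; residuals are i.i.d.
#' `N(0, noise_sd^2)` per trait and time.
#'
#' @param genotypes a [genotype_matrix()] produced by
#'   [simulate_genotypes()] with the same config.
#' @param config the [sim_config()] used for the genotypes.
#' @return list with `phenotypes` (data frame: sample_id, group, study,
#'   then `<trait>_<time>` columns) and `truth` (causal SNP/gene/pathway
#'   record with realized heritable variance fraction at T2).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  if (nrow(genotypes$dosage) != config$n_samples)
    stop("genotype sample count does not match config")
  set.seed(offset_seed(config$seed, 1000003))
  n <- config$n_samples

  causal_snps <- data.frame(snp_id = character(), gene = integer(),
                            beta = numeric(), stringsAsFactors = FALSE)
  genetic <- rep(0, n)
  if (!is.null(config$causal_genes)) {
    for (r in seq_len(nrow(config$causal_genes))) {
      gi <- config$causal_genes$gene[r]
      k <- config$causal_genes$n_snps[r]
      idx <- which(genotypes$snps$block == gi)
      if (length(idx) == 0)
        stop(sprintf("causal gene %d has no SNPs in the genotype matrix", gi))
      if (k > length(idx))
        stop(sprintf("causal gene %d has %d SNPs, %d causal requested",
                     gi, length(idx), k))
      pick <- idx[unique(round(seq(1, length(idx), length.out = k)))]
      beta <- config$causal_genes$beta[r] * config$noise_sd
      x <- genotypes$dosage[, pick, drop = FALSE]
      if (anyNA(x)) {  # generator-side fill so planted effects stay defined
        for (j in seq_len(ncol(x)))
          x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
      }
      genetic <- genetic + as.vector(x %*% rep(beta, length(pick)))
      causal_snps <- rbind(causal_snps, data.frame(
        snp_id = genotypes$snps$snp_id[pick], gene = gi, beta = beta,
        stringsAsFactors = FALSE))
    }
  }

  i_g1 <- as.numeric(genotypes$samples$group == 1)
  i_e <- as.numeric(genotypes$samples$study)
  fixed <- config$covariate_effects[["group"]] * i_g1 +
    config$covariate_effects[["study"]] * i_e

  ph <- genotypes$samples[, c("sample_id", "group", "study")]
  times <- c("T1", "T2", "T3")
  for (tr in config$traits) {
    for (tm in times) {
      mu <- config$baseline[[tm]] + fixed +
        config$time_multipliers[[tm]] * genetic
      ph[[paste(tr, tm, sep = "_")]] <-
        mu + stats::rnorm(n, 0, config$noise_sd)
    }
  }

  g2 <- config$time_multipliers[["T2"]]^2 * stats::var(genetic)
  h2_t2 <- if (g2 > 0) g2 / (g2 + config$noise_sd^2) else 0

  truth <- list(
    causal_snps = causal_snps,
    causal_genes = if (nrow(causal_snps)) sprintf("gene%03d",
                                                  unique(causal_snps$gene))
                   else character(),
    causal_pathway = if (!is.null(config$causal_pathway_index))
      sprintf("pw%02d", config$causal_pathway_index) else NA_character_,
    h2_t2 = h2_t2
  )
  list(phenotypes = ph, truth = truth)
}
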