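#' Quality-control filter for a genotype matrix
#'
#' Removes SNPs below the call-rate or minor-allele-frequency threshold
#' (both inclusive: a SNP at exactly the threshold is kept) and, when
#' `impute` is set, replaces the surviving missing entries by the SNP's
#' most frequent observed dosage (mode imputation).
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing genotypes (default
#'   0.95).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param impute replace remaining missing entries by the per-SNP mode.
#' @return a filtered [genotype_matrix()]; `attr(, "qc_report")` holds the
#'   counts of SNPs removed by each rule and of imputed entries.
#' @export
qc_filter <- function(genotypes, min_call_rate = 0.95, min_maf = 0.05,
                      impute = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  tol <- 1e-12  # guard against last-ulp noise at exact thresholds
  cr <- genotypes$snps$call_rate
  maf <- genotypes$snps$maf
  fail_cr <- cr < min_call_rate - tol
  fail_maf <- is.na(maf) | maf < min_maf - tol
  keep <- !fail_cr & !fail_maf
  if (!any(keep))
    warning("QC removed every SNP; returning an empty genotype matrix")
  dosage <- genotypes$dosage[, keep, drop = FALSE]
  n_imputed <- 0L
  if (impute && anyNA(dosage) && ncol(dosage) > 0) {
    for (j in which(colSums(is.na(dosage)) > 0)) {
      tab <- tabulate(dosage[, j] + 1L, nbins = 3L)
      mode_d <- which.max(tab) - 1L
      miss <- is.na(dosage[, j])
      dosage[miss, j] <- mode_d
      n_imputed <- n_imputed + sum(miss)
    }
  }
  out <- genotype_matrix(dosage, genotypes$snps[keep, , drop = FALSE],
                         genotypes$samples)
  attr(out, "qc_report") <- list(
    n_input = length(keep),
    removed_call_rate = sum(fail_cr),
    removed_maf = sum(fail_maf & !fail_cr),
    n_kept = sum(keep),
    n_imputed = n_imputed
  )
  out
}
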