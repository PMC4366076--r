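#' Genotype dosage matrix with per-SNP metadata
#'
#' The container every stage of the pipeline works on: an `n x m` dosage
#' matrix with values in `{0, 1, 2}` (count of the minor allele) or `NA`,
#' a SNP table (id, chromosome, 1-based position, call rate, minor allele
#' frequency) and a sample table (id, group label, study indicator).
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns.
#' @param snps data frame with at least `snp_id`, `chrom`, `pos`.
#' @param samples data frame with at least `sample_id`; `group` and `study`
#'   columns are carried when present.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  if (nrow(snps) != ncol(dosage))
    stop("snps table and dosage column count disagree")
  if (nrow(samples) != nrow(dosage))
    stop("sample table and dosage row count disagree")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or missing")
  if (any(snps$pos < 1)) stop("SNP positions must be 1-based (>= 1)")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- snps$snp_id
  snps$call_rate <- colMeans(!is.na(dosage))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  snps$maf <- pmin(p, 1 - p)
  obj <- list(dosage = dosage, snps = snps, samples = samples)
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  missing entries: %d; MAF range: %.3f-%.3f\n",
              sum(is.na(x$dosage)),
              min(x$snps$maf, na.rm = TRUE), max(x$snps$maf, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# seed arithmetic kept inside 32-bit integer range
offset_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1) + 1)
}

# draw n values uniformly from an inclusive integer range; safe when the
# range is a single value (avoids sample()'s scalar expansion)
draw_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}
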