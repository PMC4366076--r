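#' Project a phenotype onto the orthogonal complement of the covariates
#'
#' Computes the null-model residuals `y - P_Z y` with
#' `P_Z = Z (Z^t Z)^{-1} Z^t` applied through a QR decomposition (never an
#' explicit inverse) and the maximum-likelihood scale under the null,
#' `sigma_hat^2 = (1/n) ||y - P_Z y||^2`.
#'
#' @param y numeric phenotype vector (finite).
#' @param Z covariate matrix, first column the intercept.
#' @return object of class `projection_fit`: `residuals`, `sigma2`,
#'   `sigma`, `n`, `rank`, and `Q` (orthonormal basis of the column space,
#'   reused to project genotype blocks).
#' @export
project_out_covariates <- function(y, Z) {
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("phenotype contains non-finite values")
  Z <- as.matrix(Z)
  n <- length(y)
  stopifnot(nrow(Z) == n)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("covariate matrix Z^tZ is singular (rank ", qrz$rank,
         " < ", ncol(Z), " columns)")
  if (n <= qrz$rank)
    stop("need more samples than covariate rank")
  Q <- qr.Q(qrz)
  res <- y - Q %*% crossprod(Q, y)
  res <- as.numeric(res)
  sigma2 <- sum(res^2) / n
  if (sigma2 <= 1e-12 * max(1, sum(y^2) / n))
    stop("zero residual variance: phenotype lies in the covariate span")
  structure(list(residuals = res, sigma2 = sigma2, sigma = sqrt(sigma2),
                 n = n, rank = qrz$rank, Q = Q),
            class = "projection_fit")
}

#' Upper-tail p-value for a weighted chi-square quadratic form
#'
#' The null distribution of a quadratic form `sum_i lambda_i z_i^2`
#' (`z_i` i.i.d. standard normal) is approximated by matching the first
#' three cumulants `c_k = sum_i lambda_i^k` to a scaled, shifted
#' chi-square: with `a = c3/c2`, `b = c1 - c2^2/c3`, `d = c2^3/c3^2`, the
#' p-value is the upper chi-square_d tail at `(q - b)/a`.  When the third
#' cumulant vanishes (c3 <= 1e-12) the two-moment Satterthwaite match
#' (scale `c2/c1`, df `c1^2/c2`) is used instead.  Results are clamped to
#' `[0, 1]`; `q` may be a vector.
#'
#' @param q observed statistic value(s), non-negative.
#' @param lambdas eigenvalues of the quadratic form (non-negative after
#'   clipping round-off).
#' @return p-value(s) in `[0, 1]`.
#' @export
chi2_quadform_pvalue <- function(q, lambdas) {
  if (length(lambdas) == 0) stop("empty eigenvalue list")
  lambdas <- pmax(as.numeric(lambdas), 0)
  if (any(q < 0)) stop("statistic must be non-negative")
  c1 <- sum(lambdas)
  c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3)
  if (c1 <= 0) stop("all eigenvalues are zero")
  if (c3 <= 1e-12) {
    p <- stats::pchisq(q * c1 / c2, df = c1^2 / c2, lower.tail = FALSE)
  } else {
    a <- c3 / c2
    b <- c1 - c2^2 / c3
    d <- c2^3 / c3^2
    p <- stats::pchisq(pmax((q - b) / a, 0), df = d, lower.tail = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

# internal: projected gene block materials reused by the permutation engine
gene_block_materials <- function(X, Q) {
  X <- as.matrix(X)
  Xp <- X - Q %*% crossprod(Q, X)
  C <- crossprod(Xp)
  dC <- diag(C)
  keep <- dC > 1e-10
  list(Xp = Xp[, keep, drop = FALSE],
       C = C[keep, keep, drop = FALSE],
       diagC = dC[keep],
       n_dropped = sum(!keep))
}

#' SSU gene-based score test
#'
#' For a gene's genotype block `X` the score vector adjusted for
#' covariates is `U = X^t (y - P_Z y) / sigma_hat` with covariance
#' `C = (X - P_Z X)^t (X - P_Z X)`, and the test statistic is the sum of
#' squared standardized scores `SSU = U^t Diag(C)^{-1} U`.  Its
#' asymptotic null distribution is the weighted chi-square form with the
#' eigenvalues of `Diag(C)^{-1/2} C Diag(C)^{-1/2}`, evaluated by
#' [chi2_quadform_pvalue()].  SNP columns that are constant after
#' projection (`C_ii <= 1e-10`) are dropped and counted.
#'
#' @param fit a `projection_fit` from [project_out_covariates()].
#' @param X genotype block, samples x SNPs, aligned with `fit`.
#' @param gene_id optional identifier carried into the result.
#' @return list of class `gene_test`: `gene_id`, `m`, `n_dropped`, `U`,
#'   `C`, `ssu`, `lambdas`, cumulants `c1,c2,c3`, `p` (asymptotic; `NA`
#'   with `reason` if every column is degenerate).
#' @export
ssu_test <- function(fit, X, gene_id = NA_character_) {
  stopifnot(inherits(fit, "projection_fit"))
  X <- as.matrix(X)
  if (nrow(X) != fit$n) stop("genotype block not aligned with fit")
  if (ncol(X) < 1) stop("gene block needs at least one SNP")
  mat <- gene_block_materials(X, fit$Q)
  if (ncol(mat$Xp) == 0) {
    return(structure(list(gene_id = gene_id, m = 0L,
                          n_dropped = mat$n_dropped, U = numeric(0),
                          C = mat$C, ssu = NA_real_, lambdas = numeric(0),
                          c1 = NA_real_, c2 = NA_real_, c3 = NA_real_,
                          p = NA_real_, reason = "all SNPs degenerate"),
                     class = "gene_test"))
  }
  U <- as.numeric(crossprod(mat$Xp, fit$residuals)) / fit$sigma
  ssu <- sum(U^2 / mat$diagC)
  R <- mat$C / sqrt(outer(mat$diagC, mat$diagC))
  lam <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  p <- chi2_quadform_pvalue(ssu, lam)
  structure(list(gene_id = gene_id, m = ncol(mat$Xp),
                 n_dropped = mat$n_dropped, U = U, C = mat$C, ssu = ssu,
                 lambdas = lam, c1 = sum(lam), c2 = sum(lam^2),
                 c3 = sum(lam^3), p = p, reason = NA_character_),
            class = "gene_test")
}

#' Permutation p-value for the SSU test
#'
#' Permutes the phenotype entries uniformly, refits the null projection
#' and recomputes `U`, `C` (fixed, as it depends only on `X` and `Z`) and
#' SSU per permutation.  The reported p uses the add-one correction
#' `(1 + #{SSU_perm >= SSU_obs}) / (1 + n_perm)`.
#'
#' @param y phenotype vector.
#' @param X gene genotype block.
#' @param Z covariate matrix.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param residual_permutation permute the null residuals instead of the
#'   raw phenotype (for heavily covariate-confounded designs).
#' @return list: `p` (corrected), `p_raw`, `ssu_obs`, `n_perm`.
#' @export
ssu_permutation_pvalue <- function(y, X, Z, n_perm = 1000, seed = 1,
                                   residual_permutation = FALSE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  fit <- project_out_covariates(y, Z)
  obs <- ssu_test(fit, X)
  base <- if (residual_permutation) fit$residuals else y
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(length(y)))
  Yp <- matrix(base[perm_idx], nrow = length(y))
  ssu_perm <- ssu_stat_matrix(Yp, fit$Q, gene_block_materials(X, fit$Q))
  exceed <- sum(ssu_perm >= obs$ssu)
  list(p = (1 + exceed) / (1 + n_perm), p_raw = exceed / n_perm,
       ssu_obs = obs$ssu, n_perm = n_perm)
}

# internal: SSU statistics for many phenotype columns at once.
# Ymat is n x B; mat holds projected block materials; returns length-B.
ssu_stat_matrix <- function(Ymat, Q, mat) {
  Rm <- Ymat - Q %*% crossprod(Q, Ymat)
  sigma2 <- colSums(Rm^2) / nrow(Ymat)
  UT <- crossprod(mat$Xp, Rm)        # m x B
  colSums(UT^2 / mat$diagC) / sigma2
}

#' Run the gene-based score test over all mapped genes
#'
#' @param genotypes a QC'd [genotype_matrix()].
#' @param gene_map named list gene_id -> SNP column indices (from
#'   [map_snps_to_genes()]).
#' @param y phenotype vector aligned with the genotype samples (samples
#'   with missing phenotype are excluded from the fit together with their
#'   genotype rows).
#' @param Z covariate matrix for the full sample set.
#' @param genes optional gene annotation (gene_id, chrom, start, end) to
#'   carry positions into the result and order it genomically.
#' @return data frame: gene_id, chrom, start, end, n_snps, n_dropped,
#'   ssu, p; one row per gene with at least one retained SNP (failed
#'   genes keep `NA` p and an error message in `reason`).
#' @export
run_gbst <- function(genotypes, gene_map, y, Z, genes = NULL) {
  ok <- !is.na(y)
  y_use <- y[ok]
  Z_use <- as.matrix(Z)[ok, , drop = FALSE]
  fit <- project_out_covariates(y_use, Z_use)
  rows <- lapply(names(gene_map), function(gid) {
    res <- tryCatch(
      ssu_test(fit, genotypes$dosage[ok, gene_map[[gid]], drop = FALSE],
               gene_id = gid),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(gene_id = gid, n_snps = length(gene_map[[gid]]),
                        n_dropped = NA_integer_, ssu = NA_real_,
                        p = NA_real_, reason = "error",
                        stringsAsFactors = FALSE))
    data.frame(gene_id = gid, n_snps = res$m, n_dropped = res$n_dropped,
               ssu = res$ssu, p = res$p, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(genes)) {
    idx <- match(out$gene_id, genes$gene_id)
    out$chrom <- genes$chrom[idx]
    out$start <- genes$start[idx]
    out$end <- genes$end[idx]
    out <- out[order(out$chrom, out$start, out$gene_id), ,
               drop = FALSE]
    out <- out[, c("gene_id", "chrom", "start", "end", "n_snps",
                   "n_dropped", "ssu", "p", "reason")]
    rownames(out) <- NULL
  }
  out
}

#' Single-marker analysis: per-SNP regression t-tests
#'
#' Fits, for each SNP separately, the linear model with the covariates
#' `Z` plus that SNP and reports the two-sided t-test on the SNP
#' coefficient (computed by residualizing both phenotype and SNP on `Z`,
#' which reproduces the full-model t statistic exactly).
#'
#' @inheritParams run_gbst
#' @return data frame: snp_id, beta, t, p (NA with zero projected
#'   variance).
#' @export
run_sma <- function(genotypes, y, Z) {
  ok <- !is.na(y)
  y_use <- y[ok]
  Z_use <- as.matrix(Z)[ok, , drop = FALSE]
  fit <- project_out_covariates(y_use, Z_use)
  X <- genotypes$dosage[ok, , drop = FALSE]
  Xp <- X - fit$Q %*% crossprod(fit$Q, X)
  xx <- colSums(Xp^2)
  xy <- as.numeric(crossprod(Xp, fit$residuals))
  df <- fit$n - fit$rank - 1L
  if (df < 1) stop("not enough residual degrees of freedom for SMA")
  beta <- ifelse(xx > 1e-10, xy / xx, NA_real_)
  rss <- sum(fit$residuals^2) - ifelse(xx > 1e-10, xy^2 / xx, 0)
  se <- sqrt(rss / df / xx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  data.frame(snp_id = genotypes$snps$snp_id, beta = beta, t = tval, p = p,
             stringsAsFactors = FALSE)
}

#' Welch two-sample contrast of genotype-defined groups
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite degrees of
#' freedom), as used to compare phenotype means between carrier groups.
#'
#' @param values numeric phenotype values.
#' @param group_a,group_b logical masks (or index vectors) selecting the
#'   two groups.
#' @return list: `t`, `df`, `p`, group means.
#' @export
contrast_genotype_groups <- function(values, group_a, group_b) {
  a <- values[group_a]
  b <- values[group_b]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 non-missing values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
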