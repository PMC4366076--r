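#' Genotype principal component analysis
#'
#' Columns are standardized the way stratification analyses do: centered
#' at twice the allele frequency and scaled by the binomial standard
#' deviation `sqrt(p(1-p))` of the frequency estimate.  The eigenvalues
#' and per-sample scores come from the sample-by-sample covariance of the
#' standardized matrix (`M M^t / m` over the `m` retained SNPs).
#' Component signs are fixed by forcing the largest-magnitude SNP loading
#' positive so repeated runs agree exactly.
#'
#' @param genotypes a [genotype_matrix()] (complete, i.e. post-QC).
#' @param sample_subset optional character vector of sample ids (or
#'   logical/integer index) restricting the analysis, e.g. to one breed
#'   group.
#' @return object of class `pca_result`: `eigenvalues` (descending),
#'   `scores` (samples x components), `var_frac`, `sample_ids`,
#'   `n_skipped` zero-variance SNPs.
#' @export
genotype_pca <- function(genotypes, sample_subset = NULL) {
  dos <- genotypes$dosage
  ids <- genotypes$samples$sample_id
  if (!is.null(sample_subset)) {
    rows <- if (is.character(sample_subset)) match(sample_subset, ids)
            else which(rep_len(TRUE, nrow(dos)))[sample_subset]
    if (anyNA(rows)) stop("unknown sample id in sample_subset")
    dos <- dos[rows, , drop = FALSE]
    ids <- ids[rows]
  }
  if (nrow(dos) < 2 || ncol(dos) < 2)
    stop("PCA needs at least 2 samples and 2 SNPs")
  if (anyNA(dos)) stop("PCA requires complete genotypes; run qc_filter first")
  p <- colMeans(dos) / 2
  keep <- p > 0 & p < 1
  n_skipped <- sum(!keep)
  if (sum(keep) < 2) stop("fewer than 2 variable SNPs in the subset")
  M <- sweep(dos[, keep, drop = FALSE], 2, 2 * p[keep])
  M <- sweep(M, 2, sqrt(p[keep] * (1 - p[keep])), `/`)
  m <- ncol(M)
  K <- tcrossprod(M) / m
  eg <- eigen(K, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # fix signs via the largest-|.| SNP loading of each component
  for (j in seq_len(ncol(vecs))) {
    load <- crossprod(M, vecs[, j])
    if (load[which.max(abs(load))] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2, sqrt(pmax(vals * m, 0)), `*`)
  rownames(scores) <- ids
  structure(list(eigenvalues = vals,
                 scores = scores,
                 var_frac = if (sum(vals) > 0) vals / sum(vals) else vals,
                 sample_ids = ids,
                 n_skipped = n_skipped),
            class = "pca_result")
}

# TW1 upper-tail critical values (significance level -> threshold), the
# tabulated points commonly used for eigenvalue testing
tw1_table <- data.frame(
  alpha = c(0.10, 0.05, 0.01, 0.005, 0.001),
  crit = c(0.4501, 0.9793, 2.0234, 2.4224, 3.2724)
)

tw1_critical <- function(alpha) {
  tab <- tw1_table
  if (alpha >= tab$alpha[1]) return(tab$crit[1])
  if (alpha <= tab$alpha[nrow(tab)]) return(tab$crit[nrow(tab)])
  i <- findInterval(-alpha, -tab$alpha)  # alphas are decreasing
  la <- log(tab$alpha)
  w <- (la[i] - log(alpha)) / (la[i] - la[i + 1])
  tab$crit[i] + w * (tab$crit[i + 1] - tab$crit[i])
}

#' Count significant principal components with the Tracy-Widom test
#'
#' Sequential top-down testing of the eigenvalue spectrum: at each step
#' the leading remaining eigenvalue is normalized with the
#' Patterson-style centering and scaling constants, using an effective
#' marker number estimated from the moments of the remaining spectrum,
#' and compared against the TW1 critical value at `alpha`.  Testing stops
#' at the first non-significant component.
#'
#' @param pca a `pca_result` (or a numeric vector of eigenvalues).
#' @param alpha significance level (default 0.01).
#' @return integer count of significant leading components.
#' @export
tracy_widom_count <- function(pca, alpha = 0.01) {
  ev <- if (inherits(pca, "pca_result")) pca$eigenvalues else as.numeric(pca)
  ev <- ev[ev > max(ev, 0) * 1e-9]  # drop null directions (rank deficiency)
  crit <- tw1_critical(alpha)
  count <- 0L
  while (length(ev) >= 3) {
    mp <- length(ev)
    s1 <- sum(ev)
    s2 <- sum(ev^2)
    denom <- (mp - 1) * s2 - s1^2
    if (denom <= 0) break
    n_eff <- (mp + 1) * s1^2 / denom
    l1 <- mp * ev[1] / s1
    a <- sqrt(n_eff - 1)
    b <- sqrt(mp)
    mu <- (a + b)^2 / n_eff
    sig <- (a + b) / n_eff * (1 / a + 1 / b)^(1 / 3)
    x <- (l1 - mu) / sig
    if (x > crit) {
      count <- count + 1L
      ev <- ev[-1]
    } else break
  }
  count
}

#' Build the covariate matrix for association testing
#'
#' Reproduces the stratified design: an intercept column, a 0/1 subgroup
#' indicator, and principal-component columns that carry the subgroup's
#' scores and exact zeros for samples outside the subgroup (the PCA is
#' computed within the subgroup only).  With `drop_first_component` the
#' components used are 2..n_components (the default design `Z`); setting
#' `include_study_indicator` adds the study-origin column and component 1
#' (the extended design `Z*`).
#'
#' @param sample_ids character vector for the full analysis set.
#' @param group_indicator logical/0-1 vector: membership in the subgroup
#'   the PCA was computed on.
#' @param pca `pca_result` computed on exactly the subgroup samples.
#' @param n_components number of leading components deemed significant
#'   (e.g. from [tracy_widom_count()]).
#' @param drop_first_component use components 2..n (default TRUE).
#' @param include_study_indicator add the study column and component 1.
#' @param study_indicator 0/1 vector, required when
#'   `include_study_indicator` is set.
#' @return numeric matrix with labeled columns, first column all ones.
#' @export
build_covariate_matrix <- function(sample_ids, group_indicator, pca,
                                   n_components,
                                   drop_first_component = TRUE,
                                   include_study_indicator = FALSE,
                                   study_indicator = NULL) {
  n <- length(sample_ids)
  g <- as.numeric(group_indicator)
  stopifnot(length(g) == n)
  Z <- cbind(intercept = rep(1, n), group = g)
  if (include_study_indicator) {
    if (is.null(study_indicator))
      stop("study_indicator required when include_study_indicator is set")
    Z <- cbind(Z[, 1, drop = FALSE], study = as.numeric(study_indicator),
               Z[, 2, drop = FALSE])
  }
  comp <- if (n_components < 1) integer(0)
          else if (drop_first_component && !include_study_indicator) {
            if (n_components >= 2) 2:n_components else integer(0)
          } else seq_len(n_components)
  if (length(comp) > 0) {
    if (max(comp) > ncol(pca$scores))
      stop("requested more components than the PCA provides")
    sub_rows <- match(pca$sample_ids, sample_ids)
    if (anyNA(sub_rows))
      stop("PCA sample ids must be a subset of sample_ids")
    pc_cols <- matrix(0, n, length(comp),
                      dimnames = list(NULL, paste0("PC", comp)))
    pc_cols[sub_rows, ] <- pca$scores[, comp, drop = FALSE]
    Z <- cbind(Z, pc_cols)
  }
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Z
}
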