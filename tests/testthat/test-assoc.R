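test_that("null projection reproduces the hand-worked intercept example", {
  fit <- project_out_covariates(c(1, 2, 3, 4), matrix(1, 4, 1))
  expect_equal(fit$residuals, c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(fit$sigma2, 1.25)
  # residuals orthogonal to the covariate columns
  set.seed(2)
  Z <- cbind(1, stats::rnorm(20), stats::rbinom(20, 1, 0.4))
  f2 <- project_out_covariates(stats::rnorm(20), Z)
  expect_lt(max(abs(crossprod(Z, f2$residuals))), 1e-8)
  # a phenotype inside the covariate span is degenerate
  expect_error(project_out_covariates(Z %*% c(1, 2, 3), Z),
               "covariate span")
  expect_error(project_out_covariates(1:4, cbind(1:4, 2 * (1:4))),
               "singular")
})

test_that("SSU statistic matches the hand-worked single-SNP example", {
  fit <- project_out_covariates(c(1, 2, 3, 4), matrix(1, 4, 1))
  res <- ssu_test(fit, matrix(c(0, 1, 1, 2), 4, 1))
  expect_equal(res$U * fit$sigma, 3)
  expect_equal(as.numeric(res$C), 2)
  expect_equal(res$ssu, 3.6)
  expect_equal(res$c1, 1)
})

test_that("single-SNP SSU equals the squared marginal score statistic", {
  set.seed(5)
  for (i in 1:20) {
    n <- 150
    Z <- cbind(1, stats::rnorm(n))
    x <- matrix(stats::rbinom(n, 2, 0.3), ncol = 1)
    y <- stats::rnorm(n)
    fit <- project_out_covariates(y, Z)
    res <- ssu_test(fit, x)
    xp <- x - fit$Q %*% crossprod(fit$Q, x)
    u <- sum(xp * fit$residuals) / fit$sigma
    expect_equal(res$ssu, u^2 / sum(xp^2))
    expect_equal(res$p,
                 stats::pchisq(res$ssu, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("orthogonal equal-variance columns recover the chi-square_m tail", {
  # build X whose projected columns are exactly orthogonal with equal norm
  n <- 64
  Z <- matrix(1, n, 1)
  H <- stats::model.matrix(~ 0 + gl(8, n / 8))[, 1:8]
  X <- scale(H, center = TRUE, scale = FALSE)[, 1:4]
  X <- qr.Q(qr(X)) * 2    # orthonormal * 2: equal diagonal, zero cross terms
  set.seed(9)
  y <- stats::rnorm(n)
  fit <- project_out_covariates(y, Z)
  Xp <- X - fit$Q %*% crossprod(fit$Q, X)
  res_std <- tryCatch({
    C <- crossprod(Xp)
    U <- as.numeric(crossprod(Xp, fit$residuals)) / fit$sigma
    sum(U * solve(C, U))
  })
  res <- ssu_test(fit, X)
  expect_equal(res$ssu, res_std, tolerance = 1e-8)
  expect_equal(res$p, stats::pchisq(res$ssu, df = 4, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("cumulant-matched p-values reduce to exact chi-square tails", {
  expect_equal(chi2_quadform_pvalue(3.841, 1), 0.05, tolerance = 1e-3)
  q <- c(0.3, 2, 7.8)
  expect_equal(chi2_quadform_pvalue(q, rep(1, 5)),
               stats::pchisq(q, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(chi2_quadform_pvalue(1, numeric(0)), "empty")
  expect_error(chi2_quadform_pvalue(-1, 1), "non-negative")
  # a single surviving eigenvalue still reduces to its chi-square_1 tail
  expect_equal(chi2_quadform_pvalue(2, c(1, 0, 0)),
               stats::pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-10)
  # near-zero spectra fall back to the two-moment Satterthwaite match
  expect_equal(chi2_quadform_pvalue(2e-4, rep(1e-5, 10)),
               stats::pchisq(20, 10, lower.tail = FALSE), tolerance = 1e-8)
})

test_that("quadratic-form p-values match the Monte-Carlo oracle", {
  # frozen oracle: the 0.95 quantile of 2 z1^2 + z2^2 + 0.5 z3^2 from a
  # 10^6-draw simulation (seed 42) is 9.8696; the matched tail there must
  # sit at the nominal 5% level
  p <- chi2_quadform_pvalue(9.8696, c(2, 1, 0.5))
  expect_gt(p, 0.045)
  expect_lt(p, 0.055)
})

test_that("SSU and its p-value are invariant to phenotype scale", {
  set.seed(13)
  n <- 100
  Z <- cbind(1, stats::rbinom(n, 1, 0.5))
  X <- matrix(stats::rbinom(n * 6, 2, 0.25), n, 6)
  y <- stats::rnorm(n)
  a <- ssu_test(project_out_covariates(y, Z), X)
  b <- ssu_test(project_out_covariates(1000 * y, Z), X)
  expect_equal(a$ssu, b$ssu, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("degenerate SNP columns are dropped and counted", {
  set.seed(3)
  n <- 50
  Z <- matrix(1, n, 1)
  X <- cbind(stats::rbinom(n, 2, 0.3), rep(2, n), stats::rbinom(n, 2, 0.4))
  res <- ssu_test(project_out_covariates(stats::rnorm(n), Z), X)
  expect_equal(res$n_dropped, 1)
  expect_equal(res$m, 2)
  # all-degenerate block yields missing p with a reason
  res2 <- ssu_test(project_out_covariates(stats::rnorm(n), Z),
                   matrix(1, n, 2))
  expect_true(is.na(res2$p))
  expect_match(res2$reason, "degenerate")
})

test_that("permutation p-values are bounded and uniform under the null", {
  set.seed(21)
  n <- 120
  Z <- cbind(1, stats::rbinom(n, 1, 0.5))
  pp <- numeric(200)
  for (i in seq_len(200)) {
    X <- matrix(stats::rbinom(n * 8, 2, 0.3), n, 8)
    y <- stats::rnorm(n)
    pp[i] <- ssu_permutation_pvalue(y, X, Z, n_perm = 400, seed = i)$p
  }
  expect_true(all(pp >= 1 / 401 & pp <= 1))
  ks <- suppressWarnings(stats::ks.test(pp, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("asymptotic and permutation p-values agree on simulated genes", {
  set.seed(77)
  n <- 300
  Z <- cbind(1, stats::rbinom(n, 1, 0.5))
  pa <- pp <- c()
  for (i in 1:40) {
    m <- sample(2:20, 1)
    X <- matrix(stats::rbinom(n * m, 2, runif(1, 0.1, 0.4)), n, m)
    y <- stats::rnorm(n)
    pa_i <- ssu_test(project_out_covariates(y, Z), X)$p
    if (pa_i < 0.01 || pa_i > 0.5) next
    pa <- c(pa, pa_i)
    pp <- c(pp, ssu_permutation_pvalue(y, X, Z, n_perm = 10000,
                                       seed = i)$p)
  }
  expect_gt(length(pa), 10)
  expect_lt(max(abs(pa - pp)), 0.02)
})

test_that("gene-based scan ranks a planted causal gene first", {
  top <- 0
  destroyed <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_samples = 300, n_genes = 40,
                      snps_per_gene = c(15, 25), fst = 0.1, ld_rho = 0.5,
                      causal_genes = data.frame(gene = 11, n_snps = 8,
                                                beta = 0.25),
                      seed = s + 5000)
    b <- prep_cohort(cfg)
    y <- b$cohort$phenotypes$nefa_T2
    res <- run_gbst(b$geno, b$gene_map, y, b$Z, genes = b$cohort$genes)
    expect_equal(nrow(res), length(b$gene_map))
    top <- top + (res$gene_id[which.min(res$p)] == "gene011")
    # destruction control: one phenotype permutation kills the signal
    set.seed(s)
    yperm <- y[sample.int(length(y))]
    rp <- run_gbst(b$geno, b$gene_map, yperm, b$Z, genes = b$cohort$genes)
    destroyed <- destroyed + (rp$p[rp$gene_id == "gene011"] > 0.05)
  }
  expect_gte(top, 0.8 * n_seeds)
  expect_gte(destroyed, 0.9 * n_seeds)
})

test_that("single-marker analysis is calibrated and finds large effects", {
  # null uniformity
  cfg <- sim_config(n_samples = 244, n_genes = 40, snps_per_gene = c(8, 8),
                    fst = 0.05, ld_rho = 0, seed = 71)
  b <- prep_cohort(cfg)
  sma <- run_sma(b$geno, b$cohort$phenotypes$nefa_T2, b$Z)
  ks <- suppressWarnings(stats::ks.test(sma$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # a single strong SNP is the genome-wide minimum
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_samples = 300, n_genes = 40,
                      snps_per_gene = c(8, 8), fst = 0.05, ld_rho = 0.2,
                      causal_genes = data.frame(gene = 7, n_snps = 1,
                                                beta = 0.8),
                      seed = s + 6000)
    b <- prep_cohort(cfg)
    sma <- run_sma(b$geno, b$cohort$phenotypes$nefa_T2, b$Z)
    causal_id <- b$cohort$truth$causal_snps$snp_id[1]
    hits <- hits + (sma$snp_id[which.min(sma$p)] == causal_id)
  }
  expect_gte(hits, 9)
})

test_that("SMA t-test and single-SNP SSU agree asymptotically", {
  set.seed(33)
  diffs <- c()
  for (i in 1:30) {
    n <- 250
    Z <- cbind(1, stats::rbinom(n, 1, 0.5))
    x <- stats::rbinom(n, 2, 0.3)
    y <- stats::rnorm(n) + 0.08 * x
    g <- genotype_matrix(matrix(x, ncol = 1),
                         data.frame(snp_id = "s", chrom = "1", pos = 1),
                         data.frame(sample_id = paste0("S", 1:n)))
    p_t <- run_sma(g, y, Z)$p
    p_ssu <- ssu_test(project_out_covariates(y, Z),
                      matrix(x, ncol = 1))$p
    diffs <- c(diffs, abs(p_t - p_ssu))
  }
  expect_lt(max(diffs), 0.01)
})

test_that("Welch contrast matches the textbook formulas", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  res <- contrast_genotype_groups(c(a, b), rep(c(TRUE, FALSE), each = 5),
                                  rep(c(FALSE, TRUE), each = 5))
  va <- stats::var(a) / 5
  vb <- stats::var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 4 + vb^2 / 4)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * stats::pt(abs(t_hand), df_hand,
                                    lower.tail = FALSE))
  # swapping groups flips the sign, p unchanged
  swp <- contrast_genotype_groups(c(a, b), rep(c(FALSE, TRUE), each = 5),
                                  rep(c(TRUE, FALSE), each = 5))
  expect_equal(swp$t, -res$t)
  expect_equal(swp$p, res$p)
  # identical samples: t = 0, p = 1
  same <- contrast_genotype_groups(c(a, a), rep(c(TRUE, FALSE), each = 5),
                                   rep(c(FALSE, TRUE), each = 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(contrast_genotype_groups(c(1, 2, 3), c(TRUE, FALSE, FALSE),
                                        c(FALSE, TRUE, TRUE)),
               "at least 2")
})
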