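#' Rank genes by association strength
#'
#' Single-trait mode ranks by `r(g) = -log10(p)`; joint mode by the
#' product of the three per-trait p-values,
#' `r(g) = -log10(p1 * p2 * p3)`, which boosts genes small in all
#' traits.  Ties are broken by genomic position (chromosome, then start),
#' stably.
#'
#' @param p named numeric vector of per-gene p-values in (0, 1], or (in
#'   joint mode) a data frame / matrix with one column per trait and gene
#'   ids as rownames or in a `gene_id` column.
#' @param genes optional annotation (gene_id, chrom, start) supplying the
#'   tie-break order.
#' @return data frame of class `ranked_genes`: gene_id, r (non-increasing),
#'   rank.
#' @export
rank_genes <- function(p, genes = NULL) {
  if (is.data.frame(p) || is.matrix(p)) {
    p <- as.data.frame(p)
    if ("gene_id" %in% names(p)) {
      ids <- p$gene_id
      p <- p[, setdiff(names(p), "gene_id"), drop = FALSE]
    } else ids <- rownames(p)
    pm <- as.matrix(p)
    if (any(is.na(pm))) stop("joint ranking requires all trait p-values")
    pv <- apply(pm, 1, prod)
    names(pv) <- ids
  } else {
    pv <- p
    if (is.null(names(pv))) names(pv) <- as.character(seq_along(pv))
  }
  if (any(is.na(pv)) || any(pv < 0) || any(pv > 1))
    stop("p-values must lie in [0, 1] without NA")
  if (any(pv == 0)) {
    warning("p = 0 capped at the smallest positive double for ranking")
    pv[pv == 0] <- .Machine$double.xmin
  }
  r <- -log10(pv)
  if (!is.null(genes)) {
    idx <- match(names(pv), genes$gene_id)
    ord <- order(-r, genes$chrom[idx], genes$start[idx])
  } else {
    ord <- order(-r)
  }
  out <- data.frame(gene_id = names(pv)[ord], r = unname(r[ord]),
                    rank = seq_along(pv), stringsAsFactors = FALSE)
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at a pathway member with metric `r_i` the
#' running sum increases by `r_i / sum_{g in S} r_g`; at a non-member it
#' decreases by `1 / (N - N_S)`.  Increments and decrements each total 1,
#' so the walk ends at zero; the enrichment score is the running-sum
#' value of maximal absolute deviation, sign preserved.  If every member
#' metric is zero the increments fall back to equal weights `1/N_S`.
#'
#' @param ranked a `ranked_genes` data frame (or a list with `gene_id`
#'   and `r` in ranked order).
#' @param pathway character vector of member gene ids.
#' @return list: `es`, `trace` (running sum after each gene), `n_s`.
#' @export
enrichment_score <- function(ranked, pathway) {
  ids <- ranked$gene_id
  r <- ranked$r
  N <- length(ids)
  member <- ids %in% pathway
  n_s <- sum(member)
  if (n_s == 0) stop("pathway shares no gene with the ranked list")
  if (n_s == N) stop("pathway contains every listed gene; decrement undefined")
  denom <- sum(r[member])
  inc <- if (denom > 0) r / denom else rep(1 / n_s, N)
  step <- ifelse(member, inc, -1 / (N - n_s))
  trace <- cumsum(step)
  es <- trace[which.max(abs(trace))]
  list(es = es, trace = trace, n_s = n_s)
}

#' Wilcoxon rank-sum statistic of pathway members
#'
#' Sum of the 1-based positions of the member genes in the ranked list;
#' small values indicate concentration at the top.
#'
#' @inheritParams enrichment_score
#' @return list: `rs`, `n_s`.
#' @export
wrst_statistic <- function(ranked, pathway) {
  member <- ranked$gene_id %in% pathway
  n_s <- sum(member)
  if (n_s == 0) stop("pathway shares no gene with the ranked list")
  list(rs = sum(which(member)), n_s = n_s)
}

#' Phenotype-permutation null for pathway enrichment
#'
#' Repeats the full gene-based-test -> ranking -> statistic pipeline on
#' uniformly permuted phenotypes.  One shared permutation stream serves
#' all pathways: each permutation yields one permuted gene ranking, from
#' which every pathway's WKST enrichment score and WRST rank sum are
#' read.  Enrichment is one-sided toward over-representation at the top:
#' for ES the null exceedances are `ES_perm >= ES_obs`, for RS they are
#' `RS_perm <= RS_obs`.  Both the raw (`#/N`) and add-one-corrected
#' (`(1+#)/(1+N)`) p-values are reported.
#'
#' @param y phenotype vector (or matrix with one column per trait for the
#'   joint metric; columns are permuted jointly so cross-trait structure
#'   survives).
#' @param genotypes QC'd [genotype_matrix()].
#' @param Z covariate matrix.
#' @param gene_map named list gene_id -> SNP column indices.
#' @param pathways named list pathway_id -> member gene ids (already
#'   intersected with the annotation; membership is further intersected
#'   with the genes actually tested).
#' @param genes optional annotation for position tie-breaks.
#' @param n_perm number of permutations (>= 100; study-scale runs use
#'   10000).
#' @param seed RNG seed for the shared permutation stream.
#' @param residual_permutation permute null-model residuals instead of
#'   raw phenotypes.
#' @return data frame of class `enrichment_result`: pathway_id, n_s, es,
#'   es_p_raw, es_p, rs, rs_p_raw, rs_p (corrected p-values are the
#'   headline), ordered as supplied.
#' @export
permutation_null <- function(y, genotypes, Z, gene_map, pathways,
                             genes = NULL, n_perm = 1000, seed = 1,
                             residual_permutation = FALSE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  ok <- stats::complete.cases(Y)
  Y <- Y[ok, , drop = FALSE]
  Zu <- as.matrix(Z)[ok, , drop = FALSE]
  n <- nrow(Y)
  qrz <- qr(Zu)
  Q <- qr.Q(qrz)

  mats <- lapply(gene_map, function(idx)
    gene_block_materials(genotypes$dosage[ok, idx, drop = FALSE], Q))
  usable <- vapply(mats, function(m) ncol(m$Xp) > 0, logical(1))
  mats <- mats[usable]
  gene_ids <- names(mats)
  lam_list <- lapply(mats, function(m) {
    R <- m$C / sqrt(outer(m$diagC, m$diagC))
    pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  })

  gene_p_matrix <- function(Ymat) {
    # rows: genes, cols: phenotype columns
    vapply(seq_along(mats), function(gi) {
      s <- ssu_stat_matrix(Ymat, Q, mats[[gi]])
      chi2_quadform_pvalue(s, lam_list[[gi]])
    }, numeric(ncol(Ymat)))
  }

  rank_from_p <- function(pv) {
    names(pv) <- gene_ids
    suppressWarnings(rank_genes(pv, genes = genes))
  }

  obs_p <- gene_p_matrix(Y)
  obs_p <- if (ncol(Y) > 1) apply(matrix(obs_p, ncol = length(mats)), 2, prod)
           else as.numeric(obs_p)
  obs_rank <- rank_from_p(pmin(pmax(obs_p, .Machine$double.xmin), 1))

  sets <- lapply(pathways, intersect, y = gene_ids)
  keep <- lengths(sets) > 0 & lengths(sets) < length(gene_ids)
  sets <- sets[keep]
  obs_es <- vapply(sets, function(s) enrichment_score(obs_rank, s)$es,
                   numeric(1))
  obs_rs <- vapply(sets, function(s) wrst_statistic(obs_rank, s)$rs,
                   numeric(1))

  set.seed(seed)
  es_ge <- rs_le <- stats::setNames(numeric(length(sets)), names(sets))
  base <- if (residual_permutation) Y - Q %*% crossprod(Q, Y) else Y
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Yp <- base[idx, , drop = FALSE]
    pp <- gene_p_matrix(Yp)
    pp <- if (ncol(Yp) > 1) apply(matrix(pp, ncol = length(mats)), 2, prod)
          else as.numeric(pp)
    rk <- rank_from_p(pmin(pmax(pp, .Machine$double.xmin), 1))
    for (si in seq_along(sets)) {
      es <- enrichment_score(rk, sets[[si]])$es
      rs <- wrst_statistic(rk, sets[[si]])$rs
      if (es >= obs_es[si]) es_ge[si] <- es_ge[si] + 1
      if (rs <= obs_rs[si]) rs_le[si] <- rs_le[si] + 1
    }
  }
  out <- data.frame(
    pathway_id = names(sets),
    n_s = lengths(sets),
    es = obs_es,
    es_p_raw = es_ge / n_perm,
    es_p = (1 + es_ge) / (1 + n_perm),
    rs = obs_rs,
    rs_p_raw = rs_le / n_perm,
    rs_p = (1 + rs_le) / (1 + n_perm),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Rank pathways by permutation p-value
#'
#' Orders pathways by corrected permutation p, breaking ties by the
#' observed statistic (larger ES, or smaller RS), and returns the top-k
#' per method plus the intersection selection ("ranked at least k-th by
#' both methods").
#'
#' @param results an `enrichment_result` data frame.
#' @param top_k how many leading pathways to report (default 5).
#' @return list: `wkst` and `wrst` (top-k data frames with a rank
#'   column), `both` (pathway ids ranked in the top-k of both).
#' @export
rank_pathways <- function(results, top_k = 5) {
  if (nrow(results) == 0) stop("no enrichment results to rank")
  if (top_k > nrow(results))
    warning("requested top ", top_k, " of ", nrow(results),
            " pathways; returning all")
  k <- min(top_k, nrow(results))
  o_es <- order(results$es_p, -results$es)
  o_rs <- order(results$rs_p, results$rs)
  wkst <- results[o_es, c("pathway_id", "n_s", "es", "es_p_raw", "es_p")]
  wrst <- results[o_rs, c("pathway_id", "n_s", "rs", "rs_p_raw", "rs_p")]
  wkst$rank <- seq_len(nrow(wkst))
  wrst$rank <- seq_len(nrow(wrst))
  rownames(wkst) <- rownames(wrst) <- NULL
  list(wkst = utils::head(wkst, k), wrst = utils::head(wrst, k),
       both = intersect(wkst$pathway_id[seq_len(k)],
                        wrst$pathway_id[seq_len(k)]))
}
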