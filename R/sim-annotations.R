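#' Build gene and pathway annotations for a simulated cohort
#'
#' Gene intervals cover their block's SNPs (with a 100 bp margin); genes
#' whose block holds no SNP are omitted, mirroring the rule that only
#' genes with at least one intragenic SNP are annotated.  Pathways are
#' dealt from a shuffled gene list with sizes drawn from
#' `genes_per_pathway` (minimum 5 members); when the sizes exactly exhaust
#' the gene list the result is a partition.  If `causal_pathway_index` is
#' set, causal genes are swapped into that pathway (displaced members move
#' to the causal genes' original pathways, preserving all sizes).
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the matching [sim_config()].
#' @return list with `genes` (data frame: gene_id, chrom, start, end,
#'   1-based inclusive) and `pathways` (named list of gene-id vectors with
#'   a `description` attribute per element stored in
#'   `attr(pathways, "descriptions")`).
#' @export
build_annotations <- function(genotypes, config) {
  validate_sim_config(config)
  if (is.null(genotypes$snps$block))
    stop("genotype matrix carries no block metadata")
  set.seed(offset_seed(config$seed, 2000003))

  genes <- do.call(rbind, lapply(seq_len(config$n_genes), function(gi) {
    idx <- which(genotypes$snps$block == gi)
    if (length(idx) == 0) return(NULL)
    data.frame(gene_id = sprintf("gene%03d", gi),
               chrom = genotypes$snps$chrom[idx[1]],
               start = max(1L, min(genotypes$snps$pos[idx]) - 100L),
               end = max(genotypes$snps$pos[idx]) + 100L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(genes) || nrow(genes) == 0)
    stop("no gene received any SNP")

  pathways <- list()
  if (config$n_pathways > 0) {
    sizes <- draw_range(config$genes_per_pathway, config$n_pathways)
    pool <- sample(genes$gene_id)
    # deal sequentially, wrapping around if the sizes overshoot the pool
    need <- sum(sizes)
    dealt <- rep(pool, length.out = max(need, length(pool)))[seq_len(need)]
    stops <- cumsum(sizes)
    starts <- c(1, utils::head(stops, -1) + 1)
    pathways <- lapply(seq_len(config$n_pathways), function(i)
      unique(dealt[starts[i]:stops[i]]))
    names(pathways) <- sprintf("pw%02d", seq_len(config$n_pathways))

    if (!is.null(config$causal_pathway_index) &&
        !is.null(config$causal_genes)) {
      k <- config$causal_pathway_index
      causal_ids <- sprintf("gene%03d", unique(config$causal_genes$gene))
      for (cid in causal_ids) {
        if (cid %in% pathways[[k]]) next
        hosts <- which(vapply(pathways, function(p) cid %in% p, logical(1)))
        swap_pool <- setdiff(pathways[[k]], causal_ids)
        victim <- swap_pool[1]
        pathways[[k]] <- c(setdiff(pathways[[k]], victim), cid)
        if (length(hosts)) {
          for (h in hosts)
            pathways[[h]] <- c(setdiff(pathways[[h]], cid), victim)
        }
      }
    }
    attr(pathways, "descriptions") <-
      stats::setNames(sprintf("synthetic pathway %d",
                              seq_len(config$n_pathways)), names(pathways))
  }
  list(genes = genes, pathways = pathways)
}

#' Simulate a complete cohort bundle
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_phenotypes()] and [build_annotations()] under one config.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `phenotypes`, `truth`, `genes`,
#'   `pathways`, `config`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotypes(geno, config)
  ann <- build_annotations(geno, config)
  list(genotypes = geno, phenotypes = ph$phenotypes, truth = ph$truth,
       genes = ann$genes, pathways = ann$pathways, config = config)
}
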