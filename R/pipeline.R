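#' Configuration for an end-to-end analysis run
#'
#' Exactly one of `input_dir` (a directory produced by [write_cohort()],
#' or containing equivalently named files) or `sim` (a [sim_config()])
#' must be given.
#'
#' @param input_dir directory with genotypes.ped/.map, phenotypes.tsv,
#'   genes.bed, pathways.gmt.
#' @param sim a [sim_config()] generating the cohort in memory.
#' @param traits traits to analyze (default: all found).
#' @param times time points and/or ratio labels, e.g.
#'   `c("T2", "T2_T1")`; ratios are derived on the fly.
#' @param min_call_rate,min_maf QC thresholds (inclusive keeps).
#' @param flank SNP-to-gene window in bp.
#' @param n_components number of stratification components, or `"auto"`
#'   for Tracy-Widom selection at `tw_alpha`.
#' @param tw_alpha level for the Tracy-Widom test.
#' @param drop_first_component use components 2..n in the design (the
#'   default covariate set).
#' @param include_study_indicator switch to the extended design with the
#'   study column and component 1.
#' @param alpha genome-wide Bonferroni level.
#' @param q FDR level.
#' @param n_perm enrichment permutations.
#' @param top_k pathways reported per method.
#' @param joint also run the joint three-trait ranking when at least
#'   three traits are analyzed.
#' @param run_sma also run the single-marker analysis.
#' @param log_traits traits recorded as log concentrations (affects
#'   ratio phenotypes).
#' @param seed seed for every stochastic stage.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, sim = NULL, traits = NULL,
                       times = c("T2"), min_call_rate = 0.95,
                       min_maf = 0.05, flank = 5000,
                       n_components = "auto", tw_alpha = 0.01,
                       drop_first_component = TRUE,
                       include_study_indicator = FALSE, alpha = 0.05,
                       q = 0.05, n_perm = 1000, top_k = 5, joint = FALSE,
                       run_sma = TRUE, log_traits = character(),
                       seed = 1L) {
  if (is.null(input_dir) == is.null(sim))
    stop("exactly one of input_dir or sim must be supplied")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full gene-based mapping and pathway analysis
#'
#' Stages, in order: load or simulate the cohort; QC filter and mode
#' imputation; SNP-to-gene mapping; genotype PCA on the first group with
#' Tracy-Widom component selection; covariate construction; per
#' trait/time the SSU gene-based test (and optionally the single-marker
#' analysis); Bonferroni and FDR selection; gene ranking; WKST and WRST
#' permutation enrichment; report assembly.  A manifest records the
#' config hash, seed and per-stage counts.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `gbst` (per trait-time data
#'   frames), `sma`, `selection`, `enrichment`, `top_pathways`,
#'   `pca`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (!is.null(config$sim)) {
    cohort <- simulate_cohort(config$sim)
    geno <- cohort$genotypes
    pheno <- cohort$phenotypes
    genes <- cohort$genes
    pathways <- cohort$pathways
  } else {
    geno <- read_genotypes(file.path(config$input_dir, "genotypes"),
                           "ped_map")
    pheno <- read_phenotypes(file.path(config$input_dir, "phenotypes.tsv"))
    genes <- read_gene_bed(file.path(config$input_dir, "genes.bed"))
    pathways <- read_pathways(file.path(config$input_dir, "pathways.gmt"),
                              genes = genes)
    if ("group" %in% names(pheno)) {
      geno$samples$group <-
        pheno$group[match(geno$samples$sample_id, pheno$sample_id)]
      geno$samples$study <- if ("study" %in% names(pheno))
        pheno$study[match(geno$samples$sample_id, pheno$sample_id)] else 0
    }
  }

  traits <- config$traits
  avail <- unique(sub("_T[123]$", "",
                      grep("_T[123]$", names(pheno), value = TRUE)))
  if (is.null(traits)) traits <- avail
  missing_traits <- setdiff(traits, avail)
  if (length(missing_traits))
    stop("requested trait(s) not in the phenotype table: ",
         paste(missing_traits, collapse = ", "))
  ratio_times <- grep("_", config$times, value = TRUE)
  if (length(ratio_times))
    pheno <- compute_ratio_phenotypes(pheno, ratios = ratio_times,
                                      log_traits = config$log_traits)

  geno <- qc_filter(geno, config$min_call_rate, config$min_maf,
                    impute = TRUE)
  qc_report <- attr(geno, "qc_report")
  gene_map <- map_snps_to_genes(geno, genes, flank = config$flank)
  pathways <- lapply(pathways, intersect, y = names(gene_map))
  pathways <- pathways[lengths(pathways) >= 5]

  in_g1 <- geno$samples$group == 1
  pca <- genotype_pca(geno, sample_subset = geno$samples$sample_id[in_g1])
  n_comp <- if (identical(config$n_components, "auto"))
    tracy_widom_count(pca, alpha = config$tw_alpha)
  else config$n_components
  Z <- build_covariate_matrix(
    geno$samples$sample_id, in_g1, pca, n_comp,
    drop_first_component = config$drop_first_component,
    include_study_indicator = config$include_study_indicator,
    study_indicator = geno$samples$study)

  ord <- match(geno$samples$sample_id, pheno$sample_id)
  if (anyNA(ord)) stop("phenotype table is missing genotyped samples")

  gbst <- list()
  sma <- list()
  selection <- list()
  enr <- list()
  top <- list()
  for (tr in traits) {
    for (tm in config$times) {
      col <- paste(tr, tm, sep = "_")
      if (!col %in% names(pheno)) next
      y <- pheno[[col]][ord]
      key <- col
      res <- run_gbst(geno, gene_map, y, Z, genes = genes)
      gbst[[key]] <- res
      pv <- stats::setNames(res$p, res$gene_id)
      selection[[key]] <- list(
        bonferroni = bonferroni_select(pv, alpha = config$alpha,
                                       ids = names(pv)),
        fdr = bh_select(pv, q = config$q, ids = names(pv)))
      if (isTRUE(config$run_sma))
        sma[[key]] <- run_sma(geno, y, Z)
      e <- permutation_null(y, geno, Z, gene_map, pathways, genes = genes,
                            n_perm = config$n_perm,
                            seed = offset_seed(config$seed, 3000003))
      enr[[key]] <- e
      top[[key]] <- rank_pathways(e, top_k = config$top_k)
    }
  }

  if (isTRUE(config$joint) && length(traits) >= 3) {
    for (tm in config$times) {
      cols <- paste(traits[1:3], tm, sep = "_")
      if (!all(cols %in% names(pheno))) next
      Y <- as.matrix(pheno[ord, cols])
      key <- paste0("joint_", tm)
      e <- permutation_null(Y, geno, Z, gene_map, pathways, genes = genes,
                            n_perm = config$n_perm,
                            seed = offset_seed(config$seed, 4000003))
      enr[[key]] <- e
      top[[key]] <- rank_pathways(e, top_k = config$top_k)
    }
  }

  manifest <- list(
    config_hash = hash_object(unclass(config)),
    seed = config$seed,
    r_version = as.character(getRversion()),
    n_samples = nrow(geno$dosage),
    n_snps_input = qc_report$n_input,
    n_snps_kept = qc_report$n_kept,
    n_imputed = qc_report$n_imputed,
    n_genes_tested = length(gene_map),
    n_pathways = length(pathways),
    n_components = n_comp,
    analyses = names(gbst),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(gbst = gbst, sma = sma, selection = selection,
                 enrichment = enr, top_pathways = top, pca = pca,
                 covariates = Z, gene_map = gene_map, manifest = manifest),
            class = "run_result")
}

# stable content hash via serialization to a temp file (base tools only)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Export analysis reports as TSV files
#'
#' Writes, per trait/time: the gene-level result table, a Manhattan-ready
#' table (gene, chromosome, interval midpoint, -log10 p, Bonferroni and
#' FDR threshold lines), SMA tables when present, pathway top-k tables
#' per method, and a summary count table of significant genes per
#' trait/time.  A manifest TSV lists every file with its content hash.
#'
#' @param result a `run_result` from [run_analysis()].
#' @param directory output directory (created if absent).
#' @return invisibly, the manifest data frame.
#' @export
export_reports <- function(result, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", directory)
  files <- character()
  wr <- function(tab, name) {
    path <- file.path(directory, name)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  summary_rows <- list()
  for (key in names(result$gbst)) {
    res <- result$gbst[[key]]
    wr(res, paste0("gbst_", key, ".tsv"))
    sel <- result$selection[[key]]
    man <- data.frame(
      gene_id = res$gene_id, chrom = res$chrom,
      midpoint = (res$start + res$end) / 2,
      neg_log10_p = -log10(pmax(res$p, .Machine$double.xmin)),
      bonferroni_line = -log10(sel$bonferroni$threshold),
      fdr_line = if (sel$fdr$threshold > 0) -log10(sel$fdr$threshold)
                 else NA_real_)
    wr(man, paste0("manhattan_", key, ".tsv"))
    summary_rows[[key]] <- data.frame(
      analysis = key, n_genes = nrow(res),
      n_fdr = sel$fdr$n_selected,
      n_bonferroni = sel$bonferroni$n_selected)
    if (key %in% names(result$sma))
      wr(result$sma[[key]], paste0("sma_", key, ".tsv"))
  }
  for (key in names(result$top_pathways)) {
    tp <- result$top_pathways[[key]]
    wr(tp$wkst, paste0("pathways_wkst_", key, ".tsv"))
    wr(tp$wrst, paste0("pathways_wrst_", key, ".tsv"))
  }
  if (length(summary_rows))
    wr(do.call(rbind, summary_rows), "summary_counts.tsv")
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
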