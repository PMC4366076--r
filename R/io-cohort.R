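#' Write a simulated cohort to plain-text files
#'
#' Emits the file set the readers consume: PED/MAP genotypes, a dosage
#' TSV mirror, the phenotype TSV, BED gene intervals, GMT pathways and a
#' truth table of planted causal SNPs.  Writing then reading through
#' [read_genotypes()] / [read_phenotypes()] reproduces the matrices.
#'
#' @param cohort bundle from [simulate_cohort()].
#' @param directory output directory (created if absent).
#' @return invisibly, a named character vector of file paths.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory)
  }
  if (file.access(directory, 2) != 0)
    stop("directory not writable: ", directory)
  paths <- c(
    ped = file.path(directory, "genotypes.ped"),
    map = file.path(directory, "genotypes.map"),
    dosage = file.path(directory, "dosage.tsv"),
    dosage_map = file.path(directory, "dosage.map"),
    phenotypes = file.path(directory, "phenotypes.tsv"),
    genes = file.path(directory, "genes.bed"),
    pathways = file.path(directory, "pathways.gmt"),
    truth = file.path(directory, "truth.tsv")
  )
  write_ped_map(cohort$genotypes, file.path(directory, "genotypes"))
  write_tsv_dosage(cohort$genotypes, paths[["dosage"]])
  file.copy(paths[["map"]], paths[["dosage_map"]], overwrite = TRUE)
  utils::write.table(cohort$phenotypes, paths[["phenotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  write_gene_bed(cohort$genes, paths[["genes"]])
  write_gmt(cohort$pathways, paths[["pathways"]])
  tr <- cohort$truth
  truth_tab <- if (nrow(tr$causal_snps) > 0) {
    data.frame(snp_id = tr$causal_snps$snp_id,
               gene_id = sprintf("gene%03d", tr$causal_snps$gene),
               beta = tr$causal_snps$beta,
               causal_pathway = tr$causal_pathway,
               h2_t2 = tr$h2_t2, stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = character(), gene_id = character(),
               beta = numeric(), causal_pathway = character(),
               h2_t2 = numeric())
  }
  utils::write.table(truth_tab, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
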