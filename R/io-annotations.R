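#' Read a BED file of gene intervals
#'
#' BED is 0-based half-open; internally genes are stored 1-based
#' inclusive (`start = bed_start + 1`, `end = bed_end`).  Strand, if
#' present, is ignored: flanking windows are applied symmetrically.
#'
#' @param path BED file (chrom, start, end, name, ...).
#' @return data frame with gene_id, chrom, start, end.
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs at least 4 columns (name in col 4)")
  out <- data.frame(gene_id = as.character(bed[[4]]),
                    chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]) + 1L,
                    end = as.integer(bed[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed BED interval (start > end)")
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in BED")
  out
}

#' @rdname read_gene_bed
#' @param genes data frame with gene_id, chrom, start, end (1-based
#'   inclusive).
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map SNPs to genes by position with a flanking window
#'
#' A SNP is assigned to a gene iff it lies on the same chromosome within
#' `[start - flank, end + flank]` (closed boundaries).  A SNP inside two
#' overlapping windows belongs to both genes; genes that receive no SNP
#' are dropped, mirroring the rule that only genes with at least one
#' assigned SNP are analyzed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param genes data frame with gene_id, chrom, start, end.
#' @param flank symmetric window in base pairs (default 5000, i.e. up to
#'   5 kbp up- and downstream).
#' @return named list: gene_id -> integer vector of SNP column indices,
#'   ordered by chromosome then start position.
#' @export
map_snps_to_genes <- function(genotypes, genes, flank = 5000) {
  stopifnot(flank >= 0)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                 drop = FALSE]
  chrom <- genotypes$snps$chrom
  pos <- genotypes$snps$pos
  out <- lapply(seq_len(nrow(genes)), function(i) {
    which(chrom == genes$chrom[i] &
            pos >= genes$start[i] - flank &
            pos <= genes$end[i] + flank)
  })
  names(out) <- genes$gene_id
  out[lengths(out) > 0]
}

#' Read a GMT pathway file
#'
#' Each line is `pathway_id TAB description TAB gene TAB gene ...`.
#' Membership is intersected with the genes present in the annotation and
#' pathways falling below `min_genes` surviving members are dropped.
#'
#' @param path GMT file.
#' @param genes gene annotation data frame (only `gene_id` is used), or
#'   `NULL` to skip the intersection.
#' @param min_genes minimum surviving members (default 5, inclusive).
#' @return named list of gene-id vectors; descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_pathways <- function(path, genes = NULL, min_genes = 5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: no pathways read")
    return(structure(list(), descriptions = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("malformed GMT line (need id, description, >=1 gene)")
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate pathway ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  if (!is.null(genes))
    sets <- lapply(sets, intersect, y = genes$gene_id)
  keep <- lengths(sets) >= min_genes
  if (!any(keep) && length(sets) > 0)
    warning("no pathway retained >= ", min_genes, " annotated genes")
  structure(sets[keep], descriptions = stats::setNames(desc, ids)[keep])
}

#' @rdname read_pathways
#' @param pathways named list of gene-id vectors (optionally with a
#'   `descriptions` attribute).
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(pathways), names(pathways))
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, desc[[id]], pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
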