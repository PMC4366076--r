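#' Read a genotype matrix from PED/MAP or dosage TSV
#'
#' Dosage is always oriented as the count of the minor allele, computed
#' from the data: for PED input the allele with the smaller observed
#' frequency is counted (ties broken toward the lexicographically later
#' allele code, so an `A`/`B` file at MAF 0.5 counts `B`).  Missing
#' genotypes (`0 0` in PED, empty/NA in TSV) are flagged and reflected in
#' the per-SNP call rate.
#'
#' @param path for `ped_map`, the common prefix of `<path>.ped` and
#'   `<path>.map`; for `tsv_dosage`, the TSV file (first column sample_id,
#'   remaining columns one SNP each, header row of SNP ids).  A matching
#'   `<path>.map` is consulted for positions when present.
#' @param format `"ped_map"` or `"tsv_dosage"` (explicit, no sniffing).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "tsv_dosage")) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(path) else read_tsv_dosage(path)
}

read_map_file <- function(map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "snp_id", "cm", "pos")
  map
}

read_ped_map <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path))
    stop("expected ", ped_path, " and ", map_path)
  map <- read_map_file(map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  dosage <- matrix(NA_integer_, n, m)
  sample_id <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop(sprintf("PED line %d has %d fields, expected %d",
                   i, length(f), 6 + 2 * m))
    sample_id[i] <- f[2]
    a1 <- f[seq(7, by = 2, length.out = m)]
    a2 <- f[seq(8, by = 2, length.out = m)]
    if (i == 1) {
      all1 <- matrix(NA_character_, n, m)
      all2 <- matrix(NA_character_, n, m)
    }
    all1[i, ] <- a1
    all2[i, ] <- a2
  }
  for (j in seq_len(m)) {
    a <- c(all1[, j], all2[, j])
    a[a == "0"] <- NA
    codes <- sort(unique(stats::na.omit(a)))
    if (length(codes) > 2)
      stop(sprintf("SNP %s (MAP line %d) is not biallelic: %s",
                   map$snp_id[j], j, paste(codes, collapse = "/")))
    if (length(codes) == 0) next
    if (length(codes) == 1) {  # monomorphic: the unseen allele is minor
      d <- rep(0L, n)
      d[all1[, j] == "0" | all2[, j] == "0"] <- NA_integer_
      dosage[, j] <- d
      next
    }
    counted <- {
      n1 <- sum(a == codes[1], na.rm = TRUE)
      n2 <- sum(a == codes[2], na.rm = TRUE)
      if (n1 < n2) codes[1] else if (n2 < n1) codes[2] else codes[2]
    }
    d <- (all1[, j] == counted) + (all2[, j] == counted)
    d[all1[, j] == "0" | all2[, j] == "0"] <- NA
    dosage[, j] <- as.integer(d)
  }
  genotype_matrix(
    dosage,
    snps = data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                      stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  )
}

read_tsv_dosage <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("dosage TSV must start with a sample_id column")
  sample_id <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  snp_id <- colnames(dos)
  map_path <- sub("\\.tsv$", ".map", path)
  if (file.exists(map_path)) {
    map <- read_map_file(map_path)
    map <- map[match(snp_id, map$snp_id), ]
    snps <- data.frame(snp_id = snp_id, chrom = map$chrom, pos = map$pos,
                       stringsAsFactors = FALSE)
  } else {
    snps <- data.frame(snp_id = snp_id, chrom = "1",
                       pos = seq_along(snp_id), stringsAsFactors = FALSE)
  }
  genotype_matrix(dos, snps,
                  data.frame(sample_id = sample_id, stringsAsFactors = FALSE))
}

#' Write PED/MAP files for a genotype matrix
#'
#' Alleles are coded `A` (non-counted) / `B` (counted, i.e. minor) so the
#' dosage matrix round-trips through [read_genotypes()] exactly; missing
#' genotypes are written as `0 0`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(genotypes, prefix) {
  map <- data.frame(chrom = genotypes$snps$chrom,
                    snp_id = genotypes$snps$snp_id,
                    cm = 0, pos = genotypes$snps$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pair <- c("A A", "A B", "B B")
  n <- nrow(genotypes$dosage)
  ped <- vapply(seq_len(n), function(i) {
    d <- genotypes$dosage[i, ]
    g <- ifelse(is.na(d), "0 0", pair[d + 1L])
    paste(c(sprintf("FAM%04d", i), genotypes$samples$sample_id[i],
            "0", "0", "0", "-9", g), collapse = " ")
  }, character(1))
  writeLines(ped, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Write a dosage TSV mirror of a genotype matrix
#' @param genotypes a [genotype_matrix()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_tsv_dosage <- function(genotypes, path) {
  tab <- data.frame(sample_id = genotypes$samples$sample_id,
                    genotypes$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
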