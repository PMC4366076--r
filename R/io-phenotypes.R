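#' Read a phenotype table
#'
#' Expects a TSV with `sample_id`, optional `group` and `study` columns,
#' and one numeric column per trait/time (`<trait>_<time>`).  Missing
#' values stay `NA`; exclusion is per trait at analysis time (a sample
#' missing T1 is dropped from T1 and its ratios but kept for T2/T3),
#' unless downstream code requests complete cases globally.
#'
#' @param path TSV file with a header row.
#' @return data frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype TSV needs sample_id")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  trait_cols <- setdiff(names(tab), c("sample_id", "group", "study"))
  for (cl in trait_cols) {
    v <- tab[[cl]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column %s, row %d",
                     v[bad[1]], cl, bad[1]))
      tab[[cl]] <- num
    }
  }
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Derive ratio phenotypes between sampling times
#'
#' For every trait with the needed time columns, adds the later/earlier
#' concentration ratios (T2/T1, T3/T1, T3/T2 by default).  Ratios are
#' formed on the raw concentration scale; for traits recorded as log
#' concentrations (`log_traits`) the raw ratio is `exp(x_later -
#' x_earlier)`.  Setting `log_ratio = TRUE` instead returns the
#' log-difference itself.  Zero or negative denominators yield `NA` for
#' that sample with a warning.
#'
#' @param table phenotype data frame with `<trait>_<time>` columns.
#' @param ratios character vector among `"T2_T1"`, `"T3_T1"`, `"T3_T2"`.
#' @param log_traits traits whose single-time columns are log
#'   concentrations.
#' @param log_ratio return log-differences for `log_traits` instead of
#'   raw-scale ratios.
#' @return the table with `<trait>_<later>_<earlier>` columns appended.
#' @export
compute_ratio_phenotypes <- function(table,
                                     ratios = c("T2_T1", "T3_T1", "T3_T2"),
                                     log_traits = character(),
                                     log_ratio = FALSE) {
  ratios <- match.arg(ratios, several.ok = TRUE)
  cols <- names(table)
  traits <- unique(sub("_T[123]$", "",
                       grep("_T[123]$", cols, value = TRUE)))
  n_bad <- 0L
  for (tr in traits) {
    for (rt in ratios) {
      tt <- strsplit(rt, "_", fixed = TRUE)[[1]]
      later <- paste(tr, tt[1], sep = "_")
      earlier <- paste(tr, tt[2], sep = "_")
      if (!(later %in% cols) || !(earlier %in% cols)) next
      a <- table[[later]]
      b <- table[[earlier]]
      if (tr %in% log_traits) {
        val <- if (log_ratio) a - b else exp(a - b)
      } else {
        bad <- !is.na(b) & b <= 0
        n_bad <- n_bad + sum(bad)
        b[bad] <- NA
        val <- a / b
      }
      table[[paste(tr, rt, sep = "_")]] <- val
    }
  }
  if (n_bad > 0)
    warning(n_bad, " ratio value(s) dropped: non-positive denominator")
  table
}
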