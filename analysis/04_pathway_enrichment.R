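#!/usr/bin/env Rscript
# Stage 4: pathway enrichment of the gene-level results.
#
# Ranks genes by -log10 of their gene-based p-values, computes the
# weighted Kolmogorov-Smirnov enrichment score and the Wilcoxon rank-sum
# statistic per pathway, calibrates both against phenotype permutations,
# and reports the top pathways per trait plus the joint three-trait
# ranking (product of the per-trait p-values).

library(gwaspath)

cfg <- run_config(input_dir = "results/cohort",
                  traits = c("nefa", "bhba", "glucose"),
                  times = "T2", n_perm = 1000, top_k = 5, joint = TRUE,
                  run_sma = FALSE, seed = 20260923)
res <- run_analysis(cfg)
export_reports(res, "results/enrichment")

for (key in names(res$top_pathways)) {
  tp <- res$top_pathways[[key]]
  cat("\n==", key, "==\n")
  cat("WKST top pathways:\n")
  print(tp$wkst, row.names = FALSE)
  cat("WRST top pathways:\n")
  print(tp$wrst, row.names = FALSE)
  cat("ranked in the top", nrow(tp$wkst), "by both methods:",
      if (length(tp$both)) paste(tp$both, collapse = ", ") else "none",
      "\n")
}
cat("\nenrichment tables written to results/enrichment\n")
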