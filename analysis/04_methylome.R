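#!/usr/bin/env Rscript
# Stage 04 -- methylome heterogeneity: tumor-vs-normal DMRs on binned
# counts, region-to-region variable bins, APITH over DMR bins on
# purity/copy-deconvolved levels, and epiallele diversity (entropy,
# epipolymorphism, PDR) compared between copy-altered and neutral loci.
#
# Usage: Rscript analysis/04_methylome.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(sim_config(seed = seed))
res <- suppressWarnings(run_pipeline(cohort))

dmr_rows <- list(); apith_rows <- list(); epi_rows <- list(); var_rows <- list()
for (pat in names(res$stages$methylome)) {
  m <- res$stages$methylome[[pat]]
  t <- m$dmrs$table
  t$patient <- pat
  dmr_rows[[pat]] <- t[t$status != "none", ]
  apith_rows[[pat]] <- data.frame(patient = pat, apith = m$apith)
  met <- m$metrics
  met$patient <- pat
  met$altered_segment <- m$epi_altered
  epi_rows[[pat]] <- met
  levels <- vapply(m$tumor_bins, function(b) {
    b$level[match(m$tumor_bins[[1]]$bin_id, b$bin_id)]
  }, numeric(nrow(m$tumor_bins[[1]])))
  rownames(levels) <- m$tumor_bins[[1]]$bin_id
  levels <- levels[stats::complete.cases(levels), , drop = FALSE]
  vb <- variable_bins(levels, k = 500)$table
  vb$patient <- pat
  var_rows[[pat]] <- vb[vb$top, ]
  n_dmr <- sum(t$status != "none")
  cat(sprintf("%s: %d DMR bins, APITH %.2f\n", pat, n_dmr, m$apith))
}
epi_all <- do.call(rbind, epi_rows)
cmp <- compare_scna_vs_neutral(epi_all[epi_all$analyzed, ],
                               epi_all$altered_segment[epi_all$analyzed])
cat("epiallele metrics, copy-altered vs neutral loci (Wilcoxon):\n")
print(cmp, row.names = FALSE)

write.table(do.call(rbind, dmr_rows), file.path(out, "dmrs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, apith_rows), file.path(out, "apith.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(epi_all, file.path(out, "epiallele_metrics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, var_rows), file.path(out, "variable_bins.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote dmrs.tsv, apith.tsv, epiallele_metrics.tsv, variable_bins.tsv under",
    out, "\n")
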