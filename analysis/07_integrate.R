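#!/usr/bin/env Rscript
# Stage 07 -- cross-omics integration: intra- vs inter-patient distances
# per omic (Wilcoxon), MDS embedding of the expression distances, the
# correlation battery (epigenetic APITH vs SNV-ITH, RNA-ITH vs subclonal
# SCNA fraction, with purity-partialled variants), and the end-to-end
# per-patient summary table.
#
# Usage: Rscript analysis/07_integrate.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(sim_config(seed = seed))
res <- suppressWarnings(run_pipeline(cohort, out_dir = out))
s <- res$summary

cat("intra- vs inter-patient distances per omic (Wilcoxon):\n")
print(res$stages$distances, row.names = FALSE)

mds <- res$stages$mds
write.table(data.frame(sample = rownames(mds), dim1 = mds[, 1],
                       dim2 = mds[, 2]),
            file.path(out, "mds_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# correlation battery across patient-level summaries
batt <- list()
ok <- stats::complete.cases(s$apith, s$snv_ith)
if (sum(ok) >= 3) {
  batt$apith_vs_snv_ith <- correlate(s$apith[ok], s$snv_ith[ok])
}
ok2 <- stats::complete.cases(s$rna_ith, s$subclonal_scna_fraction)
if (sum(ok2) >= 3) {
  purity <- tapply(cohort$purity_ploidy$purity,
                   cohort$purity_ploidy$patient, mean)[s$patient[ok2]]
  batt$rna_ith_vs_scna_ith <- correlate(s$rna_ith[ok2],
                                        s$subclonal_scna_fraction[ok2],
                                        partial_on = purity)
}
if (length(batt)) {
  batt_df <- do.call(rbind, batt)
  batt_df$comparison <- names(batt)
  cat("correlation battery (patient-level):\n")
  print(batt_df[, c("comparison", "n", "spearman_rho", "spearman_p",
                    "pearson_r", "partial_r")], row.names = FALSE)
  write.table(batt_df, file.path(out, "correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\nper-patient summary:\n")
print(s[, c("patient", "n_regions", "snv_ith", "evolution_pattern",
            "mean_wgii", "gd", "subclonal_scna_fraction", "apith",
            "rna_ith", "til_class", "n_putative_neo")], row.names = FALSE)
cat("wrote summary.tsv, summary.json, mds_expression.tsv, correlations.tsv under",
    out, "\n")
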