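#!/usr/bin/env Rscript
# Stage 05 -- transcriptomic heterogeneity: prevalence filtering and
# log2(TPM+1), per-gene intra/inter heterogeneity quadrants, clustering
# concordance, patient RNA-ITH with saturation, and the association of
# expression with copy dosage and promoter methylation.
#
# Usage: Rscript analysis/05_rna.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(sim_config(seed = seed))
mat <- filter_normalize(cohort$expression)
cat("retained", nrow(mat), "of", nrow(cohort$expression),
    "genes after the 1-TPM/20% filter\n")

het <- heterogeneity_scores(mat, cohort$meta$patient)
conc <- clustering_concordance(mat, cohort$meta$patient)
het$concordance <- conc$concordance[match(het$gene, conc$gene)]
cat("quadrant sizes:\n")
print(table(het$quadrant))

rna_rows <- list(); sat_rows <- list()
for (p in cohort$truth$patients) {
  cols <- cohort$meta$sample[cohort$meta$patient == p$id]
  if (length(cols) < 2) next
  r <- patient_rna_ith(mat[, cols, drop = FALSE], seed = seed)
  rna_rows[[p$id]] <- data.frame(patient = p$id, rna_ith = r$score)
  sat <- r$saturation
  sat$patient <- p$id
  sat_rows[[p$id]] <- sat
}
rna_all <- do.call(rbind, rna_rows)
cat(sprintf("median patient RNA-ITH %.3f\n", stats::median(rna_all$rna_ith)))

# copy-dosage association on the arm-level segment calls
genome <- cohort$truth$genome
genes <- cohort$truth$genes
pp <- cohort$purity_ploidy
calls <- matrix("neutral", nrow(mat), nrow(cohort$meta),
                dimnames = list(rownames(mat), cohort$meta$sample))
gidx <- match(rownames(mat), genes$gene)
for (i in seq_len(nrow(cohort$meta))) {
  segs <- cohort$segments[cohort$segments$patient == cohort$meta$patient[i] &
                            cohort$segments$region == cohort$meta$region[i], ]
  ploidy <- pp$ploidy[pp$patient == cohort$meta$patient[i] &
                        pp$region == cohort$meta$region[i]]
  ok <- !is.na(gidx)
  ratio <- expected_log2ratio(
    1, (segs$major_cn + segs$minor_cn)[
      match(genes$arm[gidx[ok]],
            paste0(segs$chrom, ifelse(segs$start == 0, "p", "q")))],
    2, ploidy)
  calls[ok, i] <- call_gain_loss(ratio)
}
quad <- stats::setNames(het$quadrant, het$gene)
dos <- dosage_association(mat, calls, cohort$meta$patient, quadrants = quad)
cat("dosage shifts (paired t):\n")
print(dos$tests, row.names = FALSE)

write.table(het, file.path(out, "gene_heterogeneity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rna_all, file.path(out, "rna_ith.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, sat_rows), file.path(out, "rna_ith_saturation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dos$shifts, file.path(out, "dosage_association.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dos$enrichment, file.path(out, "dosage_quadrant_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote gene_heterogeneity.tsv, rna_ith.tsv, rna_ith_saturation.tsv,",
    "dosage_association.tsv, dosage_quadrant_enrichment.tsv under", out, "\n")
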