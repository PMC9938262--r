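#!/usr/bin/env Rscript
# Stage 06 -- immune infiltration and neoantigen evasion: marker-based
# immune cell scores, high/low TIL classification per region and patient,
# HLA-LOH timing, and the neoantigen filtering cascade with LOH and
# RNA-expression rules.
#
# Usage: Rscript analysis/06_immune.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(sim_config(seed = seed))
mat <- log2(cohort$expression + 1)
scores <- immune_scores(mat, cohort$marker_registry)
til <- classify_til(scores, cohort$meta$patient)
cat("TIL classes:", paste(sprintf("%s=%d", names(table(til$patient_class)),
                                  table(til$patient_class)), collapse = ", "),
    "\n")

timing <- classify_hla_loh_timing(cohort$hla_loh)
loh <- timing[timing$timing != "none", ]
cat("HLA-LOH patients:", length(unique(loh$patient)),
    "(", sum(loh$timing == "clonal"), "clonal alleles,",
    sum(loh$timing == "subclonal"), "subclonal )\n")

# clonality labels for the heterogeneity fraction
vf <- filter_variants(cohort$variants)
clon <- do.call(rbind, lapply(cohort$truth$patients, function(p) {
  pp <- cohort$purity_ploidy[cohort$purity_ploidy$patient == p$id, ]
  purity <- stats::setNames(pp$purity, pp$region)
  vars <- vf$kept[vf$kept$patient == p$id, ]
  va <- suppressWarnings(analyze_patient_variants(
    vars, purity, cohort$segments[cohort$segments$patient == p$id, ],
    seed = seed))
  data.frame(patient = p$id, mut_id = va$mut_ids,
             label = va$clonality$label, stringsAsFactors = FALSE)
}))
neo <- filter_neoantigens(cohort$neoantigens, timing, clonality = clon)
cat("neoantigens per patient (putative / expressed):\n")
print(neo$summary, row.names = FALSE)

sc_out <- data.frame(sample = rownames(scores), scores, check.names = FALSE)
write.table(sc_out, file.path(out, "immune_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = names(til$region_class),
                       region_class = til$region_class,
                       patient = cohort$meta$patient,
                       patient_class = til$patient_class[cohort$meta$patient]),
            file.path(out, "til_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(neo$table, file.path(out, "neoantigens.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(neo$summary, file.path(out, "neoantigen_summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote immune_scores.tsv, til_classes.tsv, neoantigens.tsv,",
    "neoantigen_summary.json under", out, "\n")
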