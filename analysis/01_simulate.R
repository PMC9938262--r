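#!/usr/bin/env Rscript
# Stage 01 -- simulate the multi-region multi-omics cohort.
#
# Generates the synthetic ESCC-like cohort with known ground truth and
# writes every input table the downstream stages consume (variants, VCF,
# allele-specific segments, purity/ploidy, CpG methylation, epiallele
# counts, TPM matrix, phased SNP BAFs, neoantigen candidates, HLA-LOH
# calls, marker registry, arm BED, truth JSON). Later stages re-derive
# the same cohort deterministically from the seed in config.yaml, so the
# written directory is the archival record, not a hand-off requirement.
#
# Usage: Rscript analysis/01_simulate.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results/cohort"

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)

n_regions <- nrow(cohort$purity_ploidy)
cat("simulated", cfg$n_patients, "patients /", n_regions, "tumor regions\n")
cat("  variant rows:", nrow(cohort$variants), ";",
    "genes:", nrow(cohort$expression), ";",
    "CpG records:", nrow(cohort$methylation), ";",
    "epiallele loci:", length(unique(cohort$epialleles$locus)), "\n")
cat("  genome-doubled patients:",
    sum(vapply(cohort$truth$patients, `[[`, TRUE, "gd")), "/",
    cfg$n_patients, "\n")
cat("  planted mirrored-arm patients:",
    sum(!vapply(cohort$truth$patients,
                function(p) is.null(p$msai), TRUE)), "\n")
cat("wrote cohort to", out, "\n")
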