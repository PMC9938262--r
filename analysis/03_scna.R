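#!/usr/bin/env Rscript
# Stage 03 -- copy-number instability: ploidy-normalized calls, arm-level
# clonal/subclonal events, wGII and genome doubling, subclonal SCNA
# fraction, and mirrored subclonal allelic imbalance from phased BAFs.
#
# Usage: Rscript analysis/03_scna.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(sim_config(seed = seed))
genome <- cohort$truth$genome
arms <- data.frame(chrom = genome$chrom, start = genome$start,
                   end = genome$end, name = paste0(genome$chrom, genome$arm))

arm_rows <- list(); wgii_rows <- list(); ith_rows <- list(); msai_rows <- list()
for (p in cohort$truth$patients) {
  pp <- cohort$purity_ploidy[cohort$purity_ploidy$patient == p$id, ]
  ploidy <- stats::setNames(pp$ploidy, pp$region)
  segs <- cohort$segments[cohort$segments$patient == p$id, ]
  seg_calls <- data.frame(
    region = segs$region, chrom = segs$chrom, start = segs$start,
    end = segs$end,
    call = call_gain_loss(expected_log2ratio(
      1, segs$major_cn + segs$minor_cn, 2, ploidy[segs$region])))
  ac <- call_arm_events(seg_calls, arms)
  ac$patient <- p$id
  arm_rows[[p$id]] <- ac[ac$call != "none", ]
  for (r in names(ploidy)) {
    w <- compute_wgii(segs[segs$region == r, ], ploidy[[r]])
    wgii_rows[[paste(p$id, r)]] <- data.frame(
      patient = p$id, region = r, wgii = w$wgii, ploidy = ploidy[[r]],
      gd = w$gd)
  }
  ith <- scna_ith_proportion(segs, ploidy)
  ith_rows[[p$id]] <- data.frame(patient = p$id,
                                 subclonal_fraction = ith$subclonal_fraction,
                                 clonal_len = ith$clonal_len,
                                 subclonal_len = ith$subclonal_len)
  msai <- detect_msai(cohort$snp_baf[cohort$snp_baf$patient == p$id, ], arms)
  if (nrow(msai)) {
    msai$patient <- p$id
    msai_rows[[p$id]] <- msai
  }
}
wgii_all <- do.call(rbind, wgii_rows)
ith_all <- do.call(rbind, ith_rows)
cat(sprintf("mean wGII %.3f; %d/%d genome-doubled regions\n",
            mean(wgii_all$wgii), sum(wgii_all$gd), nrow(wgii_all)))
cat(sprintf("median subclonal SCNA fraction %.2f\n",
            stats::median(ith_all$subclonal_fraction, na.rm = TRUE)))
cat("MSAI events detected:",
    if (length(msai_rows)) nrow(do.call(rbind, msai_rows)) else 0, "\n")
# genome doubling accompanies a larger subclonal SCNA burden (directional)
gd_pat <- vapply(cohort$truth$patients, `[[`, TRUE, "gd")
names(gd_pat) <- vapply(cohort$truth$patients, `[[`, "", "id")
by_gd <- split(ith_all$subclonal_fraction, gd_pat[ith_all$patient])
if (length(by_gd) == 2) {
  cat(sprintf("subclonal SCNA fraction, GD %.2f vs non-GD %.2f\n",
              mean(by_gd$`TRUE`, na.rm = TRUE),
              mean(by_gd$`FALSE`, na.rm = TRUE)))
}
write.table(do.call(rbind, arm_rows), file.path(out, "arm_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(wgii_all, file.path(out, "wgii.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ith_all, file.path(out, "scna_ith.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(if (length(msai_rows)) do.call(rbind, msai_rows) else
              data.frame(arm = character()),
            file.path(out, "msai_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote arm_calls.tsv, wgii.tsv, scna_ith.tsv, msai_events.tsv under",
    out, "\n")
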