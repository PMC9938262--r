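#!/usr/bin/env Rscript
# Stage 02 -- variant clonality, clone trees and mutational signatures.
#
# Filters variants with the high-quality triple rule, genotypes presence,
# estimates CCFs, clusters mutations into clones (binomial-mixture EM),
# classifies clonal / subclonal / clonal-illusion mutations, builds the
# clone tree under the cross and pigeonhole rules, and refits signature
# exposures for clonal vs subclonal mutation sets.
#
# Usage: Rscript analysis/02_clonality.R [seed] [out_dir]

suppressMessages(library(mrith))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out <- if (length(args) >= 2) args[2] else "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- simulate_cohort(sim_config(seed = seed))
vf <- filter_variants(cohort$variants)
cat("variant filter kept",
    length(unique(paste(vf$kept$patient, vf$kept$mut_id))), "mutations;",
    if (is.null(vf$rejected)) 0 else nrow(vf$rejected), "rejected\n")

clon <- list(); clus <- list(); trees <- list(); sigs <- list()
for (p in cohort$truth$patients) {
  pp <- cohort$purity_ploidy[cohort$purity_ploidy$patient == p$id, ]
  purity <- stats::setNames(pp$purity, pp$region)
  segs <- cohort$segments[cohort$segments$patient == p$id, ]
  vars <- vf$kept[vf$kept$patient == p$id, ]
  va <- suppressWarnings(analyze_patient_variants(vars, purity, segs,
                                                  seed = seed))
  clon[[p$id]] <- data.frame(
    patient = p$id, mut_id = va$mut_ids, label = va$clonality$label,
    illusion = va$clonality$illusion,
    cluster = va$clusters$assignment, stringsAsFactors = FALSE)
  prev <- va$clusters$prevalence
  clus[[p$id]] <- data.frame(
    patient = p$id,
    cluster = rep(seq_len(nrow(prev)), ncol(prev)),
    size = rep(tabulate(va$clusters$assignment, nrow(prev)), ncol(prev)),
    region = rep(p$regions, each = nrow(prev)),
    prevalence = as.vector(prev), stringsAsFactors = FALSE)
  trees[[p$id]] <- if (!is.null(va$tree)) {
    list(parents = va$tree$parents, root = va$tree$root,
         pattern = va$tree$pattern,
         prevalence = apply(va$clusters$prevalence, 1, as.list,
                            simplify = FALSE))
  } else list(error = va$tree_error)
  ch <- vars$channel[match(va$mut_ids, vars$mut_id)]
  for (lab in c("clonal", "subclonal")) {
    fit <- suppressWarnings(
      fit_signatures(ch[va$clonality$label == lab],
                     cohort$truth$signature_matrix))
    if (!fit$skipped) {
      sigs[[paste(p$id, lab)]] <- data.frame(
        patient = p$id, set = lab, signature = names(fit$exposures),
        exposure = unname(fit$exposures), residual = fit$residual)
    }
  }
  cat(sprintf("%s: %d clusters, %s evolution, SNV-ITH %.2f\n", p$id,
              va$clusters$n_clusters,
              if (!is.null(va$tree)) va$tree$pattern else "unresolved",
              va$clonality$snv_ith))
}
write.table(do.call(rbind, clon), file.path(out, "clonality.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, clus), file.path(out, "clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, sigs), file.path(out, "signatures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(trees, file.path(out, "tree.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote clonality.tsv, clusters.tsv, tree.json, signatures.tsv under",
    out, "\n")
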