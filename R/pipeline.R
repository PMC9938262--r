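#' Per-patient variant clonality analysis
#'
#' Runs the variant stage for one patient: presence genotyping, CCF
#' estimation (standard mixture form, multiplicity 1), binomial-mixture
#' clone clustering, clonal/subclonal/illusion classification (illusion
#' flags use the cluster-smoothed CCFs, which are far more stable than
#' single-mutation CCFs), and clone-tree construction.
#'
#' @param variants long variant table of one patient (already filtered).
#' @param purity named per-region purity vector.
#' @param segments per-region allele-specific segments of the patient
#'   (for local copy numbers; NULL = CN 2 everywhere).
#' @param seed RNG seed for the clustering.
#' @param eps tree feasibility tolerance.
#' @return list: presence, ccf, ccf_smoothed, clusters, clonality, tree
#'   (NULL with `tree_error` when no feasible tree exists at `eps`).
#' @export
analyze_patient_variants <- function(variants, purity, segments = NULL,
                                     seed = 1L, eps = 0.05) {
  regions <- names(purity)
  muts <- unique(variants[, c("mut_id", "chrom", "pos")])
  alt <- matrix(0L, nrow(muts), length(regions),
                dimnames = list(muts$mut_id, regions))
  dep <- alt
  idx <- cbind(match(variants$mut_id, muts$mut_id),
               match(variants$region, regions))
  alt[idx] <- variants$t_alt
  dep[idx] <- variants$t_alt + variants$t_ref
  cn <- matrix(2, nrow(muts), length(regions), dimnames = dimnames(alt))
  if (!is.null(segments)) {
    for (r in regions) {
      s <- segments[segments$region == r, ]
      cn[, r] <- vapply(seq_len(nrow(muts)), function(i) {
        w <- which(s$chrom == muts$chrom[i] & s$start <= muts$pos[i] - 1 &
                     muts$pos[i] - 1 < s$end)
        if (length(w)) s$major_cn[w[1]] + s$minor_cn[w[1]] else 2
      }, 1)
    }
  }
  presence <- genotype_presence(alt, dep)
  vaf <- ifelse(dep > 0, alt / dep, 0)
  pur <- matrix(purity, nrow(muts), length(regions), byrow = TRUE)
  ccf <- compute_ccf(vaf, pur, cn)
  clusters <- cluster_ccf(alt, dep, purity, cn, seed = seed)
  ccf_smoothed <- clusters$prevalence[clusters$assignment, , drop = FALSE]
  dimnames(ccf_smoothed) <- dimnames(alt)
  clonality <- classify_clonality(presence, ccf_smoothed)
  tree <- tryCatch(build_clone_tree(clusters$prevalence, eps = eps),
                   error = function(e) structure(list(), error = conditionMessage(e)))
  tree_error <- attr(tree, "error")
  if (!is.null(tree_error)) tree <- NULL
  list(mut_ids = muts$mut_id, presence = presence, ccf = ccf,
       ccf_smoothed = ccf_smoothed, clusters = clusters,
       clonality = clonality, tree = tree, tree_error = tree_error)
}

#' Run the full multi-omics ITH pipeline on a simulated cohort
#'
#' Executes every stage in dependency order -- variant clonality and
#' clone trees, signature refitting, SCNA instability and MSAI, methylome
#' heterogeneity and epialleles, RNA heterogeneity, immune infiltration,
#' neoantigen filtering, and cross-omics integration -- and returns a
#' per-patient summary plus the stage outputs. With `out_dir` the summary
#' is also written as TSV and JSON (the JSON is byte-stable for a fixed
#' seed).
#'
#' @param cohort a [simulate_cohort()] object.
#' @param out_dir optional output directory.
#' @param seed seed for the stochastic stages (default: the cohort's).
#' @param signatures 96 x S signature matrix for the refit stage
#'   (default: the cohort's synthetic signature matrix).
#' @return list: `summary` (per-patient data.frame), `stages` (detailed
#'   stage outputs).
#' @export
run_pipeline <- function(cohort, out_dir = NULL, seed = cohort$config$seed,
                         signatures = cohort$truth$signature_matrix) {
  genome <- cohort$truth$genome
  arms <- data.frame(chrom = genome$chrom, start = genome$start,
                     end = genome$end, name = arm_ids(genome),
                     stringsAsFactors = FALSE)
  pp <- cohort$purity_ploidy
  patients <- unique(pp$patient)

  vf <- filter_variants(cohort$variants)
  stages <- list(filter = vf)
  var_res <- list(); scna_res <- list(); meth_res <- list()
  clon_rows <- list()
  summary_rows <- list()

  expr_log2_all <- log2(cohort$expression + 1)
  expr_filt <- filter_normalize(cohort$expression)
  het <- heterogeneity_scores(expr_filt, cohort$meta$patient)
  quad <- stats::setNames(het$quadrant, het$gene)
  conc <- clustering_concordance(expr_filt, cohort$meta$patient)
  imm_scores <- immune_scores(expr_log2_all, cohort$marker_registry)
  til <- classify_til(imm_scores, cohort$meta$patient)
  hla_timing <- classify_hla_loh_timing(cohort$hla_loh)

  for (ip in seq_along(patients)) {
    pat <- patients[ip]
    ppp <- pp[pp$patient == pat, ]
    purity <- stats::setNames(ppp$purity, ppp$region)
    ploidy <- stats::setNames(ppp$ploidy, ppp$region)
    segs <- cohort$segments[cohort$segments$patient == pat, ]
    vars <- vf$kept[vf$kept$patient == pat, ]

    va <- analyze_patient_variants(vars, purity, segs,
                                   seed = derive_seed(seed, 10L + ip))
    var_res[[pat]] <- va
    clon_rows[[pat]] <- data.frame(patient = pat, mut_id = va$mut_ids,
                                   label = va$clonality$label,
                                   illusion = va$clonality$illusion,
                                   stringsAsFactors = FALSE)

    # mutational signatures, clonal vs subclonal
    ch <- vars$channel[match(va$mut_ids, vars$mut_id)]
    sig_clonal <- fit_signatures(ch[va$clonality$label == "clonal"], signatures)
    sig_subclonal <- suppressWarnings(
      fit_signatures(ch[va$clonality$label == "subclonal"], signatures))

    # SCNA stage
    seg_calls <- data.frame(
      region = segs$region, chrom = segs$chrom,
      start = segs$start, end = segs$end,
      call = call_gain_loss(expected_log2ratio(
        1, segs$major_cn + segs$minor_cn, 2,
        ploidy[segs$region])),
      stringsAsFactors = FALSE)
    arm_calls <- call_arm_events(seg_calls, arms)
    wgii <- vapply(names(purity), function(r) {
      compute_wgii(segs[segs$region == r, ], ploidy[[r]])$wgii
    }, 1)
    gd <- any(ploidy >= 3)
    ith <- if (length(purity) >= 2) {
      scna_ith_proportion(segs, ploidy)
    } else list(subclonal_fraction = NA_real_)
    baf <- cohort$snp_baf[cohort$snp_baf$patient == pat, ]
    msai <- detect_msai(baf, arms)
    scna_res[[pat]] <- list(seg_calls = seg_calls, arm_calls = arm_calls,
                            wgii = wgii, gd = gd, ith = ith, msai = msai)

    # methylome stage
    mt <- cohort$methylation[cohort$methylation$patient == pat, ]
    tumor_bins <- lapply(stats::setNames(nm = names(purity)), function(r) {
      bin_methylation(mt[mt$region == r, c("chrom", "pos", "meth_reads", "total_reads")])
    })
    normal_bins <- bin_methylation(
      mt[mt$region == "normal", c("chrom", "pos", "meth_reads", "total_reads")])
    tumor_agg <- aggregate_bins(tumor_bins)
    dmrs <- call_dmrs(tumor_agg, normal_bins)
    common_bins <- Reduce(intersect, lapply(tumor_bins, `[[`, "bin_id"))
    dmr_bins <- intersect(dmrs$table$bin_id[dmrs$table$status != "none"],
                          common_bins)
    feat_bins <- if (length(dmr_bins) >= 2) dmr_bins else common_bins
    profile <- vapply(names(tumor_bins), function(r) {
      b <- tumor_bins[[r]]
      lev <- b$level[match(feat_bins, b$bin_id)]
      nt <- segment_cn_at(segs[segs$region == r, ],
                          sub("^(.*):(\\d+)$", "\\1", feat_bins),
                          as.integer(sub("^(.*):(\\d+)$", "\\2", feat_bins)))
      mn <- normal_bins$level[match(feat_bins, normal_bins$bin_id)]
      deconvolve_methylation(lev, mn, purity[[r]], pmax(nt, 1))
    }, numeric(length(feat_bins)))
    profile <- matrix(profile, nrow = length(feat_bins),
                      dimnames = list(feat_bins, names(tumor_bins)))
    apith <- if (length(purity) >= 2) compute_apith(profile) else NA_real_

    epi <- cohort$epialleles[cohort$epialleles$patient == pat, ]
    pcols <- pattern_names()
    metrics <- epiallele_metrics(epi[, pcols])
    altered <- vapply(seq_len(nrow(epi)), function(i) {
      r <- epi$region[i]
      cn_l <- segment_cn_at(segs[segs$region == r, ], epi$chrom[i], epi$start[i])
      cn_l != round(ploidy[[r]])
    }, logical(1))
    epi_cmp <- if (any(altered) && any(!altered)) {
      compare_scna_vs_neutral(metrics[metrics$analyzed, ],
                              altered[metrics$analyzed])
    } else NULL
    meth_res[[pat]] <- list(dmrs = dmrs, apith = apith, metrics = metrics,
                            epi_altered = altered, epi_cmp = epi_cmp,
                            profile = profile, tumor_bins = tumor_bins)

    # RNA-ITH of this patient
    cols <- cohort$meta$sample[cohort$meta$patient == pat]
    rna <- if (length(cols) >= 2) {
      patient_rna_ith(expr_filt[, cols, drop = FALSE],
                      seed = derive_seed(seed, 100L + ip))
    } else NULL

    summary_rows[[pat]] <- data.frame(
      patient = pat,
      n_regions = length(purity),
      n_mutations = length(va$mut_ids),
      snv_ith = va$clonality$snv_ith,
      illusion_fraction = mean(va$clonality$illusion),
      n_clusters = va$clusters$n_clusters,
      evolution_pattern = if (!is.null(va$tree)) va$tree$pattern else NA_character_,
      sig_top_clonal = if (!sig_clonal$skipped) {
        as.integer(which.max(sig_clonal$exposures))
      } else NA_integer_,
      mean_wgii = mean(wgii),
      gd = gd,
      subclonal_scna_fraction = ith$subclonal_fraction,
      n_msai = nrow(msai),
      apith = apith,
      rna_ith = if (!is.null(rna)) rna$score else NA_real_,
      til_class = unname(til$patient_class[pat]),
      stringsAsFactors = FALSE)
  }

  clonality_all <- do.call(rbind, clon_rows)
  neo <- filter_neoantigens(cohort$neoantigens, hla_timing,
                            clonality = clonality_all)
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  summary$n_putative_neo <- neo$summary$n_putative[
    match(summary$patient, neo$summary$patient)]
  summary$n_expressed_neo <- neo$summary$n_expressed[
    match(summary$patient, neo$summary$patient)]
  summary$neo_het_fraction <- neo$summary$het_fraction[
    match(summary$patient, neo$summary$patient)]

  # cross-omics integration
  scna_profile <- scna_profile_matrix(cohort$segments, cohort$meta, genome)
  meth_profile <- methylation_profile_matrix(meth_res, cohort$meta)
  profiles <- list(scna = scna_profile, expression = expr_filt,
                   methylation = meth_profile, immune = t(imm_scores))
  dist_cmp <- omic_distances(profiles, cohort$meta$patient)
  mds <- mds_embed(attr(dist_cmp, "distances")$expression)

  result <- list(summary = summary,
                 stages = c(stages, list(
                   variants = var_res, scna = scna_res, methylome = meth_res,
                   heterogeneity = het, concordance = conc,
                   immune_scores = imm_scores, til = til,
                   hla_timing = hla_timing, neoantigens = neo,
                   distances = dist_cmp, mds = mds,
                   clonality = clonality_all)))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(schema = "mrith-summary-v1", seed = seed,
                              patients = summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' Sum binned methylation counts over regions (levels averaged)
#' @keywords internal
aggregate_bins <- function(bin_list) {
  common <- Reduce(intersect, lapply(bin_list, `[[`, "bin_id"))
  mats <- lapply(bin_list, function(b) b[match(common, b$bin_id), ])
  first <- mats[[1]]
  data.frame(
    bin_id = common,
    chrom = first$chrom,
    start = first$start,
    level = rowMeans(sapply(mats, `[[`, "level")),
    n_cpgs = first$n_cpgs,
    meth_reads = Reduce(`+`, lapply(mats, `[[`, "meth_reads")),
    total_reads = Reduce(`+`, lapply(mats, `[[`, "total_reads")),
    stringsAsFactors = FALSE)
}

#' Total copy number of the segment covering each position
#' @keywords internal
segment_cn_at <- function(segments_region, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    w <- which(segments_region$chrom == chrom[i] &
                 segments_region$start <= pos[i] &
                 pos[i] < segments_region$end)
    if (length(w)) segments_region$major_cn[w[1]] + segments_region$minor_cn[w[1]] else 2
  }, 1)
}

#' Arm-level total copy number profile matrix (arms x samples)
#'
#' Samples each arm at its midpoint, so the profile is robust to how the
#' segments were split.
#' @keywords internal
scna_profile_matrix <- function(segments, meta, genome) {
  arms <- arm_ids(genome)
  mid <- (genome$start + genome$end) %/% 2
  out <- matrix(NA_real_, length(arms), nrow(meta),
                dimnames = list(arms, meta$sample))
  for (i in seq_len(nrow(meta))) {
    s <- segments[segments$patient == meta$patient[i] &
                    segments$region == meta$region[i], ]
    out[, i] <- segment_cn_at(s, genome$chrom, mid)
  }
  out
}

#' Bulk methylation bin levels across all samples (bins x samples)
#'
#' Restricted to bins covered in every sample so the cross-omics distance
#' matrix has a common feature space.
#' @keywords internal
methylation_profile_matrix <- function(meth_res, meta) {
  cols <- list()
  for (pat in names(meth_res)) {
    tb <- meth_res[[pat]]$tumor_bins
    for (r in names(tb)) {
      cols[[paste(pat, r, sep = "_")]] <-
        stats::setNames(tb[[r]]$level, tb[[r]]$bin_id)
    }
  }
  common <- Reduce(intersect, lapply(cols, names))
  out <- vapply(cols, function(x) x[match(common, names(x))],
                numeric(length(common)))
  rownames(out) <- common
  out[, meta$sample, drop = FALSE]
}
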