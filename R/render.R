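#' Render sequencing-level genomic data from a cohort truth
#'
#' Converts clone prevalences and arm copy numbers into observable tables:
#' per-region variant read counts, allele-specific copy-number segments
#' with purity/ploidy, phased heterozygous-SNP B-allele frequencies, a
#' neoantigen candidate table and HLA-LOH calls.
#'
#' The read-count model follows the cancer-cell-fraction mixture: a
#' mutation of multiplicity 1 carried by a clone at prevalence CCF in a
#' region of purity rho and local total copy number CN has expected
#' VAF = CCF * rho / (CN * rho + 2 * (1 - rho)). Per-site depths are
#' Poisson(depth); alt counts binomial at the expected VAF. The matched
#' normal carries no variant reads.
#'
#' @param truth a [build_truth()] object.
#' @param config the [sim_config()] used to build it.
#' @return list with elements `variants`, `segments`, `purity_ploidy`,
#'   `snp_baf`, `neoantigens`, `hla_loh` (data.frames).
#' @export
render_genomics <- function(truth, config = truth$config) {
  set.seed(derive_seed(config$seed, 1L))
  genome <- truth$genome
  arms <- arm_ids(genome)
  variants <- list(); segs <- list(); pp <- list(); baf <- list()
  neo <- list(); hla <- list()

  for (pat in truth$patients) {
    k <- length(pat$regions)
    total_cn <- pat$cnA + pat$cnB
    m <- pat$mutations
    arm_row <- match(m$arm, arms)
    for (r in seq_len(k)) {
      region <- pat$regions[r]
      rho <- pat$purity[r]
      cn <- total_cn[arm_row, r]
      ccf <- pat$prevalence[m$clone, r]
      evaf <- ccf * rho / (cn * rho + 2 * (1 - rho))
      evaf[cn == 0] <- 0
      t_depth <- stats::rpois(nrow(m), config$depth)
      t_alt <- stats::rbinom(nrow(m), t_depth, pmin(evaf, 1))
      n_depth <- stats::rpois(nrow(m), config$depth)
      variants[[length(variants) + 1L]] <- data.frame(
        patient = pat$id, region = region,
        mut_id = m$mut_id, chrom = m$chrom, pos = m$pos,
        ref = m$ref, alt = m$alt, channel = m$channel,
        t_alt = t_alt, t_ref = t_depth - t_alt,
        n_alt = 0L, n_ref = n_depth,
        stringsAsFactors = FALSE
      )
      segs[[length(segs) + 1L]] <- data.frame(
        patient = pat$id, region = region,
        chrom = genome$chrom, start = genome$start, end = genome$end,
        major_cn = pmax(pat$cnA[, r], pat$cnB[, r]),
        minor_cn = pmin(pat$cnA[, r], pat$cnB[, r]),
        stringsAsFactors = FALSE
      )
      pp[[length(pp) + 1L]] <- data.frame(
        patient = pat$id, region = region,
        purity = unname(rho), ploidy = unname(pat$ploidy[r]),
        stringsAsFactors = FALSE
      )
    }
    baf[[length(baf) + 1L]] <- render_snp_baf(pat, genome, config)
    neo[[length(neo) + 1L]] <- render_neoantigens(pat, config)
    hla[[length(hla) + 1L]] <- data.frame(
      patient = pat$id,
      region = rep(pat$regions, each = length(pat$hla$alleles)),
      allele = rep(pat$hla$alleles, length(pat$regions)),
      lost = as.vector(pat$hla$lost),
      stringsAsFactors = FALSE
    )
  }
  list(variants = do.call(rbind, variants),
       segments = do.call(rbind, segs),
       purity_ploidy = do.call(rbind, pp),
       snp_baf = do.call(rbind, baf),
       neoantigens = do.call(rbind, neo),
       hla_loh = do.call(rbind, hla))
}

#' Phased heterozygous SNP read counts per arm and region
#'
#' 30 phased germline het SNPs per arm. The expected haplotype-A allele
#' fraction in a region is (rho*cnA + (1-rho)) / (rho*(cnA+cnB) + 2(1-rho));
#' each SNP's ALT allele lies on haplotype A or B (the `haplotype` column),
#' so mirrored gains show up as BAF deviations of opposite sign.
#' @keywords internal
render_snp_baf <- function(pat, genome, config, snps_per_arm = 30L) {
  arms <- arm_ids(genome)
  n_arms <- length(arms)
  k <- length(pat$regions)
  pos <- unlist(lapply(seq_len(n_arms), function(a) {
    round(seq(genome$start[a] + 1e4, genome$end[a] - 1e4, length.out = snps_per_arm))
  }))
  arm_of <- rep(seq_len(n_arms), each = snps_per_arm)
  hap <- sample(c("A", "B"), length(pos), replace = TRUE)
  out <- vector("list", k)
  for (r in seq_len(k)) {
    rho <- pat$purity[r]
    cnA <- pat$cnA[arm_of, r]; cnB <- pat$cnB[arm_of, r]
    fA <- (rho * cnA + (1 - rho)) / (rho * (cnA + cnB) + 2 * (1 - rho))
    f_alt <- ifelse(hap == "A", fA, 1 - fA)
    depth <- stats::rpois(length(pos), config$depth)
    alt <- stats::rbinom(length(pos), depth, f_alt)
    out[[r]] <- data.frame(
      patient = pat$id, region = pat$regions[r],
      chrom = genome$chrom[arm_of], pos = pos,
      ref_reads = depth - alt, alt_reads = alt, haplotype = hap,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Neoantigen candidate table for one patient
#'
#' About 30% of mutations yield one candidate peptide; percentile binding
#' ranks are drawn so that a minority pass the rank <= 2 cutoff, and RNA
#' coverage at the mutation site is Poisson with binomially sampled mutant
#' reads.
#' @keywords internal
render_neoantigens <- function(pat, config) {
  m <- pat$mutations
  take <- which(stats::runif(nrow(m)) < 0.3)
  if (!length(take)) take <- 1L
  n <- length(take)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  pep_len <- sample(9:11, n, replace = TRUE)
  peptide <- vapply(pep_len, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""), "")
  strong <- stats::runif(n) < 0.4
  rank_mut <- ifelse(strong, stats::runif(n, 0.01, 2), stats::runif(n, 2.01, 50))
  rank_wt <- stats::runif(n, 0.01, 50)
  rna_total <- stats::rpois(n, 12)
  rna_mut <- stats::rbinom(n, rna_total, 0.4)
  data.frame(
    patient = pat$id, mut_id = m$mut_id[take],
    peptide = peptide, hla_allele = sample(pat$hla$alleles, n, replace = TRUE),
    rank_mut = round(rank_mut, 3), rank_wt = round(rank_wt, 3),
    rna_total_reads = rna_total, rna_mut_reads = rna_mut,
    clone = m$clone[take],
    stringsAsFactors = FALSE
  )
}

#' Render methylome, epiallele and expression data from a cohort truth
#'
#' Bulk methylation is the purity- and copy-weighted mixture of the tumor
#' and normal rates: m_b = (rho*n_t*m_t + n_n*(1-rho)*m_n) /
#' (rho*n_t + n_n*(1-rho)). Planted DMR bins shift the tumor rate by
#' `dmr_shift`; regional-DMR bins additionally differ between regions of
#' the same tumor and feed the promoter-methylation/expression coupling.
#' Epiallele reads start from a per-locus dominant 4-CpG pattern and flip
#' each CpG independently with probability disorder/2, where loci on
#' copy-altered segments get `epiallele_scna_boost` extra disorder.
#' Expression combines a cohort-level gene baseline, per-patient offsets,
#' copy dosage, promoter-methylation repression, region noise, and the
#' two immune marker states.
#'
#' @param truth a [build_truth()] object.
#' @param config the [sim_config()] used to build it.
#' @return list with elements `methylation`, `epialleles`, `expression`
#'   (genes x regions TPM matrix), `marker_registry`, and `meta`
#'   (per-column patient/region/infiltration of the expression matrix).
#' @export
render_methylome_expression <- function(truth, config = truth$config) {
  set.seed(derive_seed(config$seed, 2L))
  genome <- truth$genome
  arms <- arm_ids(genome)
  bins <- truth$dmr_truth
  n_bins <- nrow(bins)
  cpg_off <- (1:5) * 500L  # 5 CpGs per 3-kb bin

  meth <- list(); epi <- list()
  expr_cols <- list(); meta <- list()
  base_expr <- stats::runif(config$n_genes, 2, 8)
  patient_offset <- matrix(stats::rnorm(config$n_genes * length(truth$patients),
                                        0, config$rna_inter_sd),
                           config$n_genes, length(truth$patients))
  registry <- default_marker_registry()
  marker_genes <- unlist(registry, use.names = FALSE)

  for (pi in seq_along(truth$patients)) {
    pat <- truth$patients[[pi]]
    k <- length(pat$regions)
    total_cn <- pat$cnA + pat$cnB
    bin_arm <- match(bins$arm, arms)
    gene_arm <- match(truth$genes$arm, arms)
    loci_arm <- match(truth$epiallele_loci$arm, arms)

    # per-region tumor methylation per bin (truth-level, before mixing)
    m_t_mat <- matrix(rep(bins$m_tumor, k), n_bins, k)
    if (nrow(pat$regional_dmr)) {
      for (j in seq_len(nrow(pat$regional_dmr))) {
        b <- pat$regional_dmr$bin[j]
        hi <- strsplit(pat$regional_dmr$high_regions[j], ",")[[1]]
        m_t_mat[b, ] <- 0.15
        m_t_mat[b, match(hi, pat$regions)] <- 0.85
      }
    }
    m_t_mat <- pmin(pmax(m_t_mat + stats::rnorm(n_bins * k, 0, 0.02), 0.01), 0.99)

    for (r in seq_len(k)) {
      rho <- pat$purity[r]
      n_t <- total_cn[bin_arm, r]
      m_b <- (rho * n_t * m_t_mat[, r] + 2 * (1 - rho) * bins$m_normal) /
             (rho * n_t + 2 * (1 - rho))
      m_b[n_t == 0] <- bins$m_normal[n_t == 0]
      for (ci in seq_along(cpg_off)) {
        tot <- stats::rpois(n_bins, config$depth)
        mm <- stats::rbinom(n_bins, tot, m_b)
        meth[[length(meth) + 1L]] <- data.frame(
          patient = pat$id, region = pat$regions[r],
          chrom = bins$chrom, pos = bins$start + cpg_off[ci],
          meth_reads = mm, total_reads = tot, stringsAsFactors = FALSE
        )
      }
      # epialleles
      altered <- total_cn[loci_arm, r] != round(pat$ploidy[r])
      disorder <- pmin(truth$epiallele_loci$base_disorder +
                       ifelse(altered, config$epiallele_scna_boost, 0), 1)
      epi[[length(epi) + 1L]] <- render_epialleles(
        pat$id, pat$regions[r], truth$epiallele_loci, disorder,
        config$epiallele_reads)

      # expression
      cn_gene <- total_cn[gene_arm, r]
      prom_m <- m_t_mat[truth$genes$promoter_bin, r]
      prom_base <- bins$m_tumor[truth$genes$promoter_bin]
      log2e <- base_expr + patient_offset[, pi] +
        config$dosage_effect * (cn_gene - 2) +
        config$promoter_meth_effect * (prom_m - prom_base) +
        stats::rnorm(config$n_genes, 0, config$rna_intra_sd)
      log2e <- pmax(log2e, 0)
      state <- pat$infiltration[r]
      marker_e <- stats::rnorm(length(marker_genes),
                               config$infiltration_states[[state]], 0.3)
      marker_e <- pmax(marker_e, 0)
      expr_cols[[length(expr_cols) + 1L]] <-
        c(2^log2e - 1, 2^marker_e - 1)
      meta[[length(meta) + 1L]] <- data.frame(
        patient = pat$id, region = pat$regions[r],
        sample = paste(pat$id, pat$regions[r], sep = "_"),
        infiltration = unname(state), stringsAsFactors = FALSE
      )
    }
    # matched-normal methylation (one per patient)
    for (ci in seq_along(cpg_off)) {
      tot <- stats::rpois(n_bins, config$depth)
      mm <- stats::rbinom(n_bins, tot, bins$m_normal)
      meth[[length(meth) + 1L]] <- data.frame(
        patient = pat$id, region = "normal",
        chrom = bins$chrom, pos = bins$start + cpg_off[ci],
        meth_reads = mm, total_reads = tot, stringsAsFactors = FALSE
      )
    }
  }
  meta <- do.call(rbind, meta)
  expression <- do.call(cbind, expr_cols)
  rownames(expression) <- c(truth$genes$gene, marker_genes)
  colnames(expression) <- meta$sample
  list(methylation = do.call(rbind, meth),
       epialleles = do.call(rbind, epi),
       expression = expression,
       marker_registry = registry,
       meta = meta)
}

#' Epiallele pattern counts for one region
#'
#' Each locus has a dominant 4-bit methylation pattern; every read flips
#' each CpG independently with probability disorder/2, so disorder = 0
#' emits a single pattern and disorder = 1 is maximally mixed.
#' @keywords internal
render_epialleles <- function(patient, region, loci, disorder, n_reads) {
  n <- nrow(loci)
  dominant <- sample.int(16L, n, replace = TRUE) - 1L
  counts <- matrix(0L, n, 16L)
  bit <- function(x, b) bitwAnd(bitwShiftR(x, b), 1L)
  for (i in seq_len(n)) {
    flip <- matrix(stats::runif(n_reads * 4L) < disorder[i] / 2, n_reads, 4L)
    bits <- matrix(vapply(0:3, function(b) bit(dominant[i], b), 1L),
                   n_reads, 4L, byrow = TRUE)
    bits <- (bits + flip) %% 2L
    pat <- bits %*% c(1L, 2L, 4L, 8L)
    counts[i, ] <- tabulate(pat + 1L, nbins = 16L)
  }
  colnames(counts) <- pattern_names()
  data.frame(patient = patient, region = region,
             locus = loci$locus, chrom = loci$chrom, start = loci$start,
             counts, stringsAsFactors = FALSE)
}

#' The 16 four-CpG epiallele pattern labels ("c0000" ... "c1111")
#' @export
pattern_names <- function() {
  paste0("c", vapply(0:15, function(x) {
    paste(rev(as.integer(intToBits(x))[1:4]), collapse = "")
  }, ""))
}

#' Default immune marker-gene registry
#'
#' Synthetic marker symbols for the 16 immune cell populations scored by
#' the pipeline (3 markers each). Real analyses substitute curated lists;
#' the simulator expresses these genes at the high/low infiltration
#' states.
#' @export
default_marker_registry <- function() {
  pops <- c("CD4_T", "TH1", "Treg", "dendritic", "B_cell", "mast", "NK",
            "NK_CD56neg", "neutrophils", "macrophages", "CD45", "CD8_T",
            "CD8_exhausted", "T_cells", "total_TIL", "cytotoxic")
  registry <- lapply(pops, function(p) paste0("MK_", p, "_", 1:3))
  names(registry) <- pops
  registry
}

#' Simulate a complete multi-region multi-omics cohort
#'
#' Convenience wrapper: [build_truth()] plus both renderers.
#' @param config a [sim_config()].
#' @return object of class "mrith_cohort": the truth plus all rendered
#'   tables.
#' @export
simulate_cohort <- function(config = sim_config()) {
  truth <- build_truth(config)
  gen <- render_genomics(truth, config)
  ome <- render_methylome_expression(truth, config)
  cohort <- c(list(truth = truth, config = config), gen, ome)
  class(cohort) <- "mrith_cohort"
  cohort
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L) + offset
}

#' @export
print.mrith_cohort <- function(x, ...) {
  cat("mrith cohort:", length(x$truth$patients), "patients,",
      nrow(x$purity_ploidy), "regions,", nrow(x$variants), "variant rows\n")
  invisible(x)
}
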