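#' Simulation configuration for a synthetic multi-region cohort
#'
#' Bundles and validates every tunable of the cohort generator. Defaults
#' emulate the study conditions of a multi-region esophageal squamous cell
#' carcinoma cohort at desk scale: 3-5 regions per patient, mean sequencing
#' depth 100x, pathology-grade purity 0.6-0.9, ~70% of patients genome
#' doubled, one third carrying a mirrored allelic-imbalance event, and
#' immune infiltration split into high / low / heterogeneous patients at
#' roughly the 21% / 45% / 33% proportions reported for such cohorts.
#'
#' @param n_patients number of patients.
#' @param regions_per_patient integer range c(min, max) of regions sampled
#'   per patient.
#' @param n_clones integer range c(min, max) of clones per patient
#'   (including the truncal clone).
#' @param depth mean sequencing depth; per-site depths are Poisson(depth).
#' @param purity numeric range c(min, max) in (0, 1]; per-region purity is
#'   uniform on it.
#' @param n_mutations expected number of mutations per clone.
#' @param genome arm table (chrom, arm, start, end), 0-based half-open.
#' @param gd_fraction fraction of patients with whole-genome doubling.
#' @param msai_fraction fraction of patients with one planted mirrored
#'   subclonal allelic-imbalance arm.
#' @param n_cpg_bins number of 3-kb methylation bins (5 CpGs each).
#' @param dmr_fraction fraction of bins planted as tumor-vs-normal DMRs
#'   (split evenly hyper/hypo); planted shift is `dmr_shift`.
#' @param dmr_shift absolute tumor-vs-normal methylation shift in planted
#'   DMR bins (>= 0.30 so DMRs are recoverable at moderate depth).
#' @param n_regional_dmr_bins number of bins made differentially methylated
#'   *between regions* of the same tumor (drives promoter-methylation /
#'   expression coupling and variable-bin analyses).
#' @param epiallele_disorder range c(min, max) of the per-locus disorder
#'   parameter in [0, 1]; each sequenced read flips each of the 4 CpGs of
#'   the locus independently with probability disorder/2.
#' @param epiallele_scna_boost added to the disorder of loci lying on
#'   copy-number-altered segments (0 decouples epiallele disorder from
#'   SCNA).
#' @param n_epiallele_loci number of 4-CpG epiallele loci.
#' @param epiallele_reads reads per epiallele locus per region.
#' @param n_genes number of (non-marker) genes in the expression matrix.
#' @param dosage_effect log2 expression shift per copy away from 2.
#' @param promoter_meth_effect log2 expression shift per unit increase of
#'   promoter methylation (negative: hypermethylation silences).
#' @param rna_inter_sd SD of per-gene patient offsets (between-tumor
#'   expression heterogeneity).
#' @param rna_intra_sd SD of per-gene region noise (within-tumor
#'   expression heterogeneity).
#' @param infiltration_states named numeric c(low=, high=): mean log2
#'   expression of immune marker genes in the two infiltration states.
#' @param infiltration_probs probabilities that a patient is uniformly
#'   high, uniformly low, or heterogeneous (named vector, sums to 1).
#' @param hla_loh_clonal_fraction,hla_loh_subclonal_fraction fractions of
#'   patients with clonal / subclonal loss of one HLA allele.
#' @param couple_gd_instability logical; genome-doubled patients get a
#'   higher arm-event rate and a larger subclonal share of events.
#' @param seed integer seed; identical seed + config give byte-identical
#'   cohorts.
#' @return validated list of class "mrith_config".
#' @export
sim_config <- function(n_patients = 6L,
                       regions_per_patient = c(3L, 5L),
                       n_clones = c(2L, 5L),
                       depth = 100,
                       purity = c(0.6, 0.9),
                       n_mutations = 30L,
                       genome = default_genome(),
                       gd_fraction = 0.7,
                       msai_fraction = 1 / 3,
                       n_cpg_bins = 200L,
                       dmr_fraction = 0.1,
                       dmr_shift = 0.4,
                       n_regional_dmr_bins = 20L,
                       epiallele_disorder = c(0.02, 0.25),
                       epiallele_scna_boost = 0.2,
                       n_epiallele_loci = 120L,
                       epiallele_reads = 80L,
                       n_genes = 400L,
                       dosage_effect = 0.5,
                       promoter_meth_effect = -2,
                       rna_inter_sd = 1.5,
                       rna_intra_sd = 0.3,
                       infiltration_states = c(low = 2, high = 6),
                       infiltration_probs = c(high = 7 / 33, low = 15 / 33, het = 11 / 33),
                       hla_loh_clonal_fraction = 0.25,
                       hla_loh_subclonal_fraction = 0.06,
                       couple_gd_instability = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_config(cfg)
  class(cfg) <- "mrith_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1)
  if (length(cfg$regions_per_patient) == 1L) {
    cfg$regions_per_patient <- rep(cfg$regions_per_patient, 2L)
  }
  if (any(cfg$regions_per_patient < 1)) stop("regions_per_patient must be positive")
  if (any(cfg$n_clones < 1)) stop("n_clones must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (any(cfg$purity <= 0) || any(cfg$purity > 1)) stop("purity must lie in (0, 1]")
  if (cfg$n_mutations < 1) stop("n_mutations must be positive")
  if (cfg$dmr_fraction < 0 || cfg$dmr_fraction > 1) stop("dmr_fraction must lie in [0, 1]")
  if (any(cfg$epiallele_disorder < 0) || any(cfg$epiallele_disorder > 1)) {
    stop("epiallele_disorder must lie in [0, 1]")
  }
  if (cfg$n_cpg_bins < 1 || cfg$n_genes < 1 || cfg$n_epiallele_loci < 1) {
    stop("counts must be positive")
  }
  if (abs(sum(cfg$infiltration_probs) - 1) > 1e-9) stop("infiltration_probs must sum to 1")
  # feasibility: the mini-genome must hold the requested CpG bins
  genome_len <- sum(cfg$genome$end - cfg$genome$start)
  if (cfg$n_cpg_bins * 3000 > genome_len) {
    stop("infeasible config: n_cpg_bins * 3kb exceeds the genome length (",
         genome_len, " bp); shrink n_cpg_bins or enlarge the genome")
  }
  max_clones <- max(cfg$n_clones)
  if (max_clones > 40) {
    stop("infeasible config: n_clones > 40 cannot satisfy the pigeonhole ",
         "constraint at a resolvable prevalence floor")
  }
  invisible(cfg)
}

#' @export
print.mrith_config <- function(x, ...) {
  cat("mrith simulation config:", x$n_patients, "patients,",
      paste(x$regions_per_patient, collapse = "-"), "regions,",
      paste(x$n_clones, collapse = "-"), "clones, depth", x$depth,
      ", seed", x$seed, "\n")
  invisible(x)
}
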