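# shared fixtures: one small cohort, simulated once per test run
small_config <- function(seed = 11L, ...) {
  sim_config(n_patients = 4L, regions_per_patient = c(3L, 4L),
             n_cpg_bins = 80L, n_genes = 120L, n_epiallele_loci = 40L,
             n_mutations = 20L, seed = seed, ...)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    .cohort_cache$co <- simulate_cohort(small_config())
  }
  .cohort_cache$co
}

arms_table <- function(genome = default_genome()) {
  data.frame(chrom = genome$chrom, start = genome$start, end = genome$end,
             name = paste0(genome$chrom, genome$arm),
             stringsAsFactors = FALSE)
}

# planted four-quadrant expression cohort: per-gene intra (within-patient)
# and inter (between-patient) dispersions set by class
plant_quadrants <- function(n_per = 40, patients = 10, regions = 4,
                            hi_intra = 2, lo_intra = 0.1,
                            hi_inter = 2, lo_inter = 0.1, seed = 1) {
  set.seed(seed)
  pat <- rep(paste0("P", seq_len(patients)), each = regions)
  n <- 4 * n_per
  intra_sd <- rep(c(hi_intra, lo_intra, hi_intra, lo_intra), each = n_per)
  inter_sd <- rep(c(lo_inter, lo_inter, hi_inter, hi_inter), each = n_per)
  truth <- rep(c("I", "II", "III", "IV"), each = n_per)
  mat <- matrix(0, n, length(pat),
                dimnames = list(sprintf("g%03d", 1:n), NULL))
  for (g in seq_len(n)) {
    offs <- rnorm(patients, 5, inter_sd[g])
    mat[g, ] <- rnorm(length(pat), offs[as.integer(factor(pat))], intra_sd[g])
  }
  list(mat = mat, patients = pat, truth = truth)
}

# ten neoantigen candidates covering every rule branch; hand-derived:
#  1 putative+expressed            6 excluded (subclonal LOH, all clones lost)
#  2 rejected (wt binds better)    7 putative, 4 RNA reads -> not expressed
#  3 rejected (rank > 2)           8 putative, 2 mutant reads -> not expressed
#  4 excluded (clonal LOH)         9 putative+expressed (boundary rank 2.0)
#  5 putative (subclonal LOH,     10 skipped (missing rank)
#    carrying clone not lost)
neo_fixture <- function() {
  data.frame(
    patient = "P1",
    mut_id = sprintf("M%02d", 1:10),
    peptide = strrep("A", 9),
    hla_allele = c("A1", "A1", "A1", "B1", "C1", "C1", "A1", "A1", "A1", "A1"),
    rank_mut = c(0.5, 1.5, 2.5, 0.5, 0.5, 0.5, 0.5, 0.5, 2.0, NA),
    rank_wt = c(5, 1.0, 50, 5, 5, 5, 5, 5, 2.0, 1),
    rna_total_reads = c(10, 10, 10, 10, 10, 10, 4, 10, 10, 10),
    rna_mut_reads = c(5, 5, 5, 5, 5, 5, 4, 2, 5, 5),
    clone = c(1, 1, 1, 1, 2, 3, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

# brute-force epiallele oracle: expand pattern counts into individual reads
# and accumulate every metric read by read
epiallele_oracle <- function(counts) {
  counts <- as.matrix(counts)
  t(apply(counts, 1, function(x) {
    reads <- rep(seq_len(16), x)  # one entry per read
    n <- length(reads)
    p <- table(factor(reads, levels = 1:16)) / n
    p <- as.numeric(p)
    ent <- 0
    for (pp in p) if (pp > 0) ent <- ent - pp * log2(pp)
    epi <- 1 - sum(p * p)
    pdr <- mean(reads != 1 & reads != 16)
    c(entropy = ent, epipolymorphism = epi, pdr = pdr)
  }))
}
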