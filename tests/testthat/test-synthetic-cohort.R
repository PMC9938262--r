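test_that("config validation rejects impossible settings", {
  expect_error(sim_config(purity = c(0, 0.9)), "purity")
  expect_error(sim_config(dmr_fraction = 1.5), "dmr_fraction")
  expect_error(sim_config(n_cpg_bins = 10^9), "infeasible")
  expect_error(sim_config(n_clones = c(1, 50)), "infeasible")
  expect_s3_class(sim_config(), "mrith_config")
})

test_that("identical seed and config give identical cohorts", {
  a <- simulate_cohort(small_config(seed = 7L))
  b <- simulate_cohort(small_config(seed = 7L))
  expect_identical(a$variants, b$variants)
  expect_identical(a$expression, b$expression)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$truth$patients, b$truth$patients)
})

test_that("a single clone makes every mutation clonal at prevalence 1", {
  tr <- build_truth(sim_config(n_patients = 2L, n_clones = c(1L, 1L),
                               seed = 5L))
  for (p in tr$patients) {
    expect_equal(unname(p$prevalence), matrix(1, 1, length(p$regions)))
    expect_true(all(p$mutations$clone == 1L))
  }
})

test_that("sampled clone trees always satisfy cross and pigeonhole rules", {
  # brute-force validator over every parent-child pair and sibling set
  n_checked <- 0
  for (s in 1:10) {
    tr <- build_truth(sim_config(n_patients = 10L, seed = 2000L + s))
    for (p in tr$patients) {
      n_checked <- n_checked + 1
      expect_true(validate_clone_tree(p$prevalence, p$parents, eps = 1e-12))
    }
  }
  expect_gte(n_checked, 100)
})

test_that("cohorts contain both linear and branched patients", {
  tr <- build_truth(sim_config(n_patients = 6L, seed = 3L))
  pats <- vapply(tr$patients, function(p) {
    kids <- tabulate(p$parents[p$parents > 0], nbins = length(p$parents))
    if (all(kids <= 1)) "linear" else "branched"
  }, character(1))
  expect_true("linear" %in% pats)
  expect_true("branched" %in% pats)
})

test_that("rendered VAFs converge to the CCF mixture expectation at high depth", {
  cfg <- sim_config(n_patients = 1L, depth = 1e5, seed = 21L)
  tr <- build_truth(cfg)
  gen <- render_genomics(tr, cfg)
  p <- tr$patients[[1]]
  v <- gen$variants
  cn_arm <- p$cnA + p$cnB
  m <- p$mutations
  for (r in p$regions) {
    vr <- v[v$region == r, ]
    rho <- p$purity[[r]]
    cn <- cn_arm[match(m$arm, rownames(cn_arm)), r]
    expected <- p$prevalence[m$clone, r] * rho / (cn * rho + 2 * (1 - rho))
    observed <- vr$t_alt / (vr$t_alt + vr$t_ref)
    expect_lt(max(abs(observed - expected[match(vr$mut_id, m$mut_id)])), 0.01)
  }
})

test_that("planted mirrored arm shows opposite BAF deviations across regions", {
  cfg <- sim_config(n_patients = 6L, msai_fraction = 1, seed = 9L)
  tr <- build_truth(cfg)
  gen <- render_genomics(tr, cfg)
  found <- 0
  for (p in tr$patients) {
    if (is.null(p$msai) || length(p$regions) < 2) next
    found <- found + 1
    baf <- gen$snp_baf[gen$snp_baf$patient == p$id, ]
    genome <- tr$genome
    a <- which(paste0(genome$chrom, genome$arm) == p$msai$arm)
    on_arm <- baf$chrom == genome$chrom[a] &
      baf$pos >= genome$start[a] & baf$pos < genome$end[a]
    fA <- ifelse(baf$haplotype == "A",
                 baf$alt_reads / (baf$alt_reads + baf$ref_reads),
                 baf$ref_reads / (baf$alt_reads + baf$ref_reads))
    mean_a <- mean(fA[on_arm & baf$region %in% p$msai$regions_a])
    mean_b <- mean(fA[on_arm & baf$region %in% p$msai$regions_b])
    expect_gt(mean_a, 0.5)
    expect_lt(mean_b, 0.5)
  }
  expect_gte(found, 3)
})

test_that("bulk methylation mixes tumor and normal rates by purity and copies", {
  # at purity 1 the bulk rate IS the tumor rate; at purity 0.7 applying the
  # deconvolution with the true purity and local copies recovers the tumor
  # rate within binomial sampling error
  agg_levels <- function(ome, region, n_bins) {
    m <- ome$methylation[ome$methylation$region == region, ]
    bin_idx <- rep(seq_len(n_bins), times = nrow(m) / n_bins)
    as.numeric(tapply(m$meth_reads, bin_idx, sum) /
                 tapply(m$total_reads, bin_idx, sum))
  }
  cfg <- sim_config(n_patients = 1L, purity = c(1, 1), depth = 2000,
                    n_cpg_bins = 60L, n_regional_dmr_bins = 0L, seed = 13L)
  tr <- build_truth(cfg)
  ome <- render_methylome_expression(tr, cfg)
  lev <- agg_levels(ome, "R1", 60L)
  expect_lt(stats::median(abs(lev - tr$dmr_truth$m_tumor)), 0.03)

  cfg2 <- sim_config(n_patients = 1L, purity = c(0.7, 0.7), depth = 5000,
                     n_cpg_bins = 60L, n_regional_dmr_bins = 0L, seed = 13L)
  tr2 <- build_truth(cfg2)
  ome2 <- render_methylome_expression(tr2, cfg2)
  p2 <- tr2$patients[[1]]
  agg <- agg_levels(ome2, "R1", 60L)
  cn_arm <- (p2$cnA + p2$cnB)[, "R1"]
  n_t <- cn_arm[tr2$dmr_truth$arm]
  m_t <- deconvolve_methylation(agg, tr2$dmr_truth$m_normal,
                                p2$purity[["R1"]], n_t)
  expect_lt(stats::median(abs(m_t - tr2$dmr_truth$m_tumor)), 0.06)
})

test_that("zero epiallele disorder emits a single pattern per locus", {
  cfg <- sim_config(n_patients = 1L, epiallele_disorder = c(0, 0),
                    epiallele_scna_boost = 0, n_epiallele_loci = 20L,
                    seed = 31L)
  tr <- build_truth(cfg)
  ome <- render_methylome_expression(tr, cfg)
  counts <- as.matrix(ome$epialleles[, pattern_names()])
  expect_true(all(rowSums(counts > 0) == 1))
})

test_that("cohort round-trips through the plain-text directory exactly", {
  co <- cached_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$variants, co$variants, ignore_attr = TRUE)
  expect_equal(back$segments, co$segments, ignore_attr = TRUE)
  expect_equal(back$epialleles, co$epialleles, ignore_attr = TRUE)
  expect_equal(unname(back$expression), unname(co$expression),
               tolerance = 1e-8)
  # referential integrity: truth lists every patient present in the omic files
  truth_ids <- vapply(back$truth$patients, `[[`, "", "id")
  for (tab in list(back$variants, back$segments, back$methylation,
                   back$epialleles, back$hla_loh)) {
    expect_true(all(unique(tab$patient) %in% truth_ids))
  }
})

test_that("VCF export re-imports with identical per-region read counts", {
  co <- cached_cohort()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$variants, path)
  back <- read_vcf_counts(path)
  key <- function(d) paste(d$patient, d$region, d$mut_id)
  back <- back[order(key(back)), ]
  orig <- co$variants[order(key(co$variants)), ]
  expect_equal(back$t_alt, orig$t_alt)
  expect_equal(back$t_ref, orig$t_ref)
  expect_equal(back$pos, orig$pos)
})
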