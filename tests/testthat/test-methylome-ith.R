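test_that("methylation deconvolution inverts the purity-copy mixture", {
  expect_equal(deconvolve_methylation(0.5, 0.8, 1, 2), 0.5)  # purity 1
  expect_equal(deconvolve_methylation(0.5, 0.8, 0.5, 2), 0.2)
  expect_equal(deconvolve_methylation(0.3, 0.8, 0.5, 2), 0)  # raw -0.2 clamped
  expect_equal(deconvolve_methylation(0.3, 0.8, 0.5, 2, clamp = FALSE), -0.2)
  expect_error(deconvolve_methylation(0.5, 0.8, 0, 2), "purity")
  expect_warning(out <- deconvolve_methylation(0.5, 0.8, 0.5, 0), "n_t = 0")
  expect_true(is.na(out))
})

test_that("binning averages CpG levels and drops sparse bins", {
  cpgs <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                     meth_reads = c(2, 4, 6), total_reads = 10)
  b <- bin_methylation(cpgs, bin_size = 3000)
  expect_equal(b$level, 0.4)
  expect_equal(b$bin_id, "chr1:0")
  # two CpGs only: dropped
  expect_equal(nrow(bin_methylation(cpgs[1:2, ], 3000)), 0)
  # empty input gives an empty profile
  expect_equal(nrow(bin_methylation(cpgs[0, ], 3000)), 0)
  # unsorted input is sorted internally; duplicates are an error
  expect_equal(bin_methylation(cpgs[c(3, 1, 2), ], 3000)$level, 0.4)
  expect_error(bin_methylation(rbind(cpgs, cpgs[1, ]), 3000), "duplicate")
})

sim_bins <- function(rate, n_cpgs = 5, depth = 60, chrom_prefix = "b") {
  # one bin per rate entry, aggregated counts at the given depth
  n <- length(rate)
  tot <- rpois(n, depth * n_cpgs)
  meth <- rbinom(n, tot, rate)
  data.frame(bin_id = paste0(chrom_prefix, seq_len(n)), chrom = "chr1",
             start = (seq_len(n) - 1) * 1000, level = meth / tot,
             n_cpgs = n_cpgs, meth_reads = meth, total_reads = tot,
             stringsAsFactors = FALSE)
}

test_that("DMR calling recovers planted shifts and controls the null", {
  set.seed(10)
  base <- runif(300, 0.2, 0.5)
  tumor_rate <- base
  tumor_rate[1:30] <- base[1:30] + 0.4  # planted hyper bins
  tumor <- sim_bins(tumor_rate)
  normal <- sim_bins(base)
  res <- call_dmrs(tumor, normal)
  expect_gte(mean(res$table$status[1:30] == "hyper"), 0.9)
  expect_lte(mean(res$table$status[-(1:30)] != "none"), 0.02)
  # tumor identical to normal: zero DMRs
  same <- call_dmrs(normal, normal)
  expect_true(all(same$table$status == "none"))
  expect_error(call_dmrs(tumor, sim_bins(base, chrom_prefix = "z")), "share")
})

test_that("DMRs placed in one element class enrich that class", {
  set.seed(11)
  base <- runif(200, 0.3, 0.5)
  tumor_rate <- base
  tumor_rate[1:20] <- base[1:20] + 0.4
  ann <- data.frame(bin_id = paste0("b", c(1:20, 150:180)),
                    element = rep(c("promoter", "LINE-1"), c(20, 31)))
  res <- call_dmrs(sim_bins(tumor_rate, depth = 100), sim_bins(base, depth = 100),
                   annotations = ann)
  prom <- res$enrichment[res$enrichment$element == "promoter", ]
  expect_gt(prom$odds_ratio, 1)
  expect_lt(prom$q, 0.05)
  # cross-check the 2x2 against a direct Fisher oracle
  hits <- res$table$bin_id[res$table$status != "none"]
  in_el <- res$table$bin_id %in% paste0("b", 1:20)
  is_hit <- res$table$bin_id %in% hits
  oracle <- stats::fisher.test(table(factor(is_hit, c(TRUE, FALSE)),
                                     factor(in_el, c(TRUE, FALSE))))
  expect_equal(prom$p, oracle$p.value)
})

test_that("variable bins rank by cross-region dispersion", {
  lev <- matrix(0.4, 50, 4, dimnames = list(paste0("b", 1:50), NULL))
  vb <- variable_bins(lev, k = 10)
  expect_true(all(vb$table$sd == 0))
  expect_equal(vb$table$bin_id[1:3], c("b1", "b10", "b11"))  # stable tie order
  lev["b42", ] <- c(0.1, 0.9, 0.1, 0.9)
  expect_equal(variable_bins(lev, k = 10)$table$bin_id[1], "b42")
  expect_warning(all_bins <- variable_bins(lev, k = 100), "exceeds")
  expect_equal(sum(all_bins$table$top), 50)
})

test_that("APITH is the mean pairwise distance between regions", {
  x <- matrix(c(0, 0, 3, 4), 2, 2)
  expect_equal(compute_apith(x), 5)  # k = 2: the single distance
  # k = 3 with pairwise distances 1, 2, 3 averages to 2
  y <- matrix(c(0, 1, 3), 1, 3)
  expect_equal(compute_apith(y), 2)
  expect_equal(compute_apith(matrix(0.5, 10, 4)), 0)
  expect_error(compute_apith(matrix(1, 5, 1)), "at least 2")
})

test_that("epiallele metrics equal the brute-force read enumeration", {
  set.seed(12)
  counts <- matrix(rpois(20 * 16, 6), 20, 16,
                   dimnames = list(NULL, pattern_names()))
  counts <- counts + 3  # keep every locus above the 60-read threshold
  m <- epiallele_metrics(counts)
  oracle <- epiallele_oracle(counts)
  expect_lt(max(abs(m$entropy - oracle[, "entropy"])), 1e-12)
  expect_lt(max(abs(m$epipolymorphism - oracle[, "epipolymorphism"])), 1e-12)
  expect_lt(max(abs(m$pdr - oracle[, "pdr"])), 1e-12)
})

test_that("epiallele metrics hit their closed-form anchor points", {
  pure <- matrix(0, 1, 16, dimnames = list(NULL, pattern_names()))
  pure[1, "c1111"] <- 80
  m <- epiallele_metrics(pure)
  expect_equal(m$entropy, 0)
  expect_equal(m$epipolymorphism, 0)
  expect_equal(m$pdr, 0)
  unif <- matrix(5, 1, 16, dimnames = list(NULL, pattern_names()))
  mu <- epiallele_metrics(unif)
  expect_equal(mu$entropy, 4)
  expect_equal(mu$epipolymorphism, 0.9375)
  expect_equal(mu$pdr, 0.875)
  mixed <- matrix(0, 1, 16, dimnames = list(NULL, pattern_names()))
  mixed[1, "c0000"] <- 48; mixed[1, "c1010"] <- 12
  expect_equal(epiallele_metrics(mixed)$pdr, 0.2)
  # below the coverage threshold: reported but unanalyzed
  low <- matrix(2, 1, 16, dimnames = list(NULL, pattern_names()))
  expect_true(is.na(epiallele_metrics(low)$entropy))
  expect_error(epiallele_metrics(mixed - 100), "negative")
})

test_that("epiallele disorder coupled to SCNA separates the strata", {
  set.seed(14)
  mk_counts <- function(n, disorder) {
    t(vapply(seq_len(n), function(i) {
      flips <- matrix(runif(80 * 4) < disorder / 2, 80, 4)
      tabulate(flips %*% c(1L, 2L, 4L, 8L) + 1L, 16L)
    }, numeric(16)))
  }
  counts <- rbind(mk_counts(100, 0.35), mk_counts(100, 0.05))
  colnames(counts) <- pattern_names()
  m <- epiallele_metrics(counts)
  altered <- rep(c(TRUE, FALSE), each = 100)
  cmp <- compare_scna_vs_neutral(m, altered)
  expect_lt(cmp$p[cmp$metric == "entropy"], 0.05)
  expect_gt(stats::median(m$entropy[altered]),
            stats::median(m$entropy[!altered]))
  # single-locus stratum: computed but flagged low-n
  cmp1 <- compare_scna_vs_neutral(m[1:3, ], c(TRUE, FALSE, FALSE))
  expect_true(all(cmp1$low_n))
  expect_false(anyNA(cmp1$p))
})
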