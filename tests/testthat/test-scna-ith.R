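test_that("expected log2 ratio matches the purity-copy mixture", {
  expect_equal(expected_log2ratio(1, 2, 2, 2), 0)
  expect_equal(expected_log2ratio(0.5, 4, 2, 2), log2(3 / 2))
  expect_equal(expected_log2ratio(0.5, 0, 2, 2), -1)
  expect_equal(expected_log2ratio(1, 0, 2, 2), -10)  # floored -Inf
  expect_error(expected_log2ratio(0.5, 2, 2, 0), "ploidy")
})

test_that("gain/loss/amp thresholds sit at 2.5, 1.5 and 4 copies", {
  expect_equal(call_gain_loss(0), "neutral")
  expect_equal(call_gain_loss(0.33), "gain")
  expect_equal(call_gain_loss(log2(2.5 / 2) - 1e-9), "neutral")
  expect_equal(call_gain_loss(1.0), "amp")
  expect_equal(call_gain_loss(log2(1.5 / 2)), "loss")
  expect_equal(call_gain_loss(c(-1, 0.4, 1.2)), c("loss", "gain", "amp"))
})

test_that("arm-level calls follow the 75/90 percent rules", {
  expect_equal(arm_call_from_fractions(c(0.80, 0.92, 0.78), c(0, 0, 0)),
               "clonal_gain")
  expect_equal(arm_call_from_fractions(c(0.80, 0.80, 0.80), c(0, 0, 0)),
               "subclonal_gain")
  expect_equal(arm_call_from_fractions(c(0.50, 0.60), c(0, 0)), "none")
  expect_equal(arm_call_from_fractions(c(0, 0), c(0.95, 0.80)), "clonal_loss")
  expect_equal(arm_call_from_fractions(c(0, 0.9), c(0, 0)), "subclonal_gain")
  # idempotence: recomputing calls from stored fractions reproduces them
  set.seed(1)
  for (i in 1:50) {
    fg <- runif(3); fl <- pmin(runif(3), 1 - fg)
    expect_identical(arm_call_from_fractions(fg, fl),
                     arm_call_from_fractions(fg, fl))
  }
  # full path from segment calls
  arms <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 300),
                     name = c("chr1p", "chr1q"))
  segs <- data.frame(region = rep(c("R1", "R2"), each = 2),
                     chrom = "chr1", start = c(0, 100, 0, 100),
                     end = c(100, 300, 100, 300),
                     call = c("gain", "neutral", "gain", "neutral"))
  calls <- call_arm_events(segs, arms)
  expect_equal(calls$call[calls$arm == "chr1p"], "clonal_gain")
  expect_equal(calls$call[calls$arm == "chr1q"], "none")
  bad <- segs; bad$chrom <- "chr9"
  expect_error(call_arm_events(bad, arms), "absent")
})

test_that("wGII counts aberrant fraction per autosome against rounded ploidy", {
  genome <- default_genome()
  base <- data.frame(chrom = genome$chrom, start = genome$start,
                     end = genome$end, major_cn = 1L, minor_cn = 1L)
  expect_equal(compute_wgii(base, 2)$wgii, 0)
  aber <- base
  aber$major_cn[aber$chrom == "chr5"] <- 2L
  expect_equal(compute_wgii(aber, 2)$wgii, 1 / 22)
  expect_true(compute_wgii(base, 3.2)$gd)
  expect_false(compute_wgii(base, 2.1)$gd)
  # splitting a segment leaves wGII unchanged
  split <- rbind(aber, aber[aber$chrom == "chr1", ])
  split$end[split$chrom == "chr1"][1:2] <- c(1e6, 1e6)
  split$start[nrow(split) - 1:0] <- 1e6
  expect_equal(compute_wgii(split, 2)$wgii, compute_wgii(aber, 2)$wgii)
  # missing autosome excluded with a warning
  expect_warning(w <- compute_wgii(base[base$chrom != "chr22", ], 2),
                 "without coverage")
  expect_equal(w$wgii, 0)
})

test_that("subclonal SCNA fraction uses minimal breakpoint intervals", {
  ploidy <- c(R1 = 2, R2 = 2)
  # identical profiles: everything altered is clonal
  segs <- data.frame(region = rep(c("R1", "R2"), each = 2),
                     chrom = rep(c("chr1", "chr2"), 2),
                     start = 0, end = 100,
                     major_cn = c(2L, 1L, 2L, 1L), minor_cn = 1L)
  expect_equal(scna_ith_proportion(segs, ploidy)$subclonal_fraction, 0)
  # equal-length private gain on chr2 in R1 only: half the altered genome
  segs2 <- data.frame(region = rep(c("R1", "R2"), each = 2),
                      chrom = rep(c("chr1", "chr2"), 2),
                      start = 0, end = 100,
                      major_cn = c(2L, 2L, 2L, 1L), minor_cn = 1L)
  expect_equal(scna_ith_proportion(segs2, ploidy)$subclonal_fraction, 0.5)
  # no alterations anywhere: NA
  segs3 <- data.frame(region = c("R1", "R2"), chrom = "chr1",
                      start = 0, end = 100, major_cn = 1L, minor_cn = 1L)
  expect_true(is.na(scna_ith_proportion(segs3, ploidy)$subclonal_fraction))
  expect_error(scna_ith_proportion(segs3[1, ], ploidy[1]), ">= 2 regions")
})

mk_baf <- function(fA_by_region, n_snps = 30, depth = 100, arm_len = 1000,
                   seed = 1) {
  set.seed(seed)
  out <- list()
  pos <- round(seq(10, arm_len - 10, length.out = n_snps))
  for (r in names(fA_by_region)) {
    hap <- sample(c("A", "B"), n_snps, replace = TRUE)
    f_alt <- ifelse(hap == "A", fA_by_region[[r]], 1 - fA_by_region[[r]])
    dep <- rpois(n_snps, depth)
    alt <- rbinom(n_snps, dep, f_alt)
    out[[r]] <- data.frame(chrom = "chr1", pos = pos, region = r,
                           ref_reads = dep - alt, alt_reads = alt,
                           haplotype = hap, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

test_that("MSAI detection requires significant opposite deviations", {
  arms <- data.frame(chrom = "chr1", start = 0, end = 1000, name = "chr1p")
  hit <- detect_msai(mk_baf(list(R1 = 0.75, R2 = 0.25)), arms)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$arm, "chr1p")
  # same direction in both regions: no event
  expect_equal(nrow(detect_msai(mk_baf(list(R1 = 0.75, R2 = 0.75)), arms)), 0)
  # balanced arm: no event
  expect_equal(nrow(detect_msai(mk_baf(list(R1 = 0.5, R2 = 0.5)), arms)), 0)
  # too few SNPs: skipped with warning
  expect_warning(
    none <- detect_msai(mk_baf(list(R1 = 0.75, R2 = 0.25), n_snps = 5), arms),
    "fewer than")
  expect_equal(nrow(none), 0)
  # low-coverage SNPs are discarded before testing
  b <- mk_baf(list(R1 = 0.75, R2 = 0.25))
  b$ref_reads <- 3L; b$alt_reads <- 3L
  expect_equal(nrow(detect_msai(b, arms)), 0)
})

test_that("null arms stay below the nominal MSAI false-positive rate", {
  arms <- data.frame(chrom = "chr1", start = 0, end = 1000, name = "chr1p")
  hits <- 0
  for (i in 1:200) {
    hits <- hits + nrow(detect_msai(mk_baf(list(R1 = 0.5, R2 = 0.5),
                                           seed = i), arms))
  }
  expect_lte(hits / 200, 0.05)
})
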