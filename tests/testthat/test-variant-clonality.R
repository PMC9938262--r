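mk_variant <- function(t_alt, t_ref, n_alt = 0, n_ref = 100,
                       region = "R1", mut = "M1", patient = "P1") {
  data.frame(patient = patient, region = region, mut_id = mut,
             t_alt = t_alt, t_ref = t_ref, n_alt = n_alt, n_ref = n_ref,
             stringsAsFactors = FALSE)
}

test_that("variant filter applies the three high-quality rules", {
  # tumor VAF 0.10 with 10 alt reads, clean normal: kept
  kept <- filter_variants(mk_variant(10, 90, 1, 99))
  expect_equal(nrow(kept$kept), 1)
  expect_null(kept$rejected)
  # four variant reads in the normal: removed by the normal-support rule
  rej <- filter_variants(mk_variant(10, 90, 4, 396))
  expect_equal(nrow(rej$kept), 0)
  expect_equal(rej$rejected$reason, "normal_support")
  # tumor depth 9: below the depth rule
  rej2 <- filter_variants(mk_variant(5, 4))
  expect_equal(nrow(rej2$kept), 0)
  expect_equal(rej2$rejected$reason, "depth")
  # zero-depth site fails the depth rule without erroring
  expect_equal(nrow(filter_variants(mk_variant(0, 0))$kept), 0)
  # kept when any region passes: all rows of the mutation survive
  two <- rbind(mk_variant(10, 90, region = "R1"),
               mk_variant(0, 100, region = "R2"))
  expect_equal(nrow(filter_variants(two)$kept), 2)
  expect_error(filter_variants(mk_variant(10, 90, NA, NA)), "normal")
})

test_that("presence genotyping uses the VAF-or-read-count rule", {
  alt <- matrix(c(3, 4, 2), 3, 1)
  dep <- matrix(c(100, 400, 100), 3, 1)
  # VAF 0.03 > 0.02 -> present; alt 4 > 3 -> present; VAF 0.02 & alt 2 -> absent
  expect_equal(as.vector(genotype_presence(alt, dep)),
               c(TRUE, TRUE, FALSE))
})

test_that("CCF follows the standard mixture rearrangement", {
  expect_equal(compute_ccf(0, 0.5, 2), 0)
  expect_equal(compute_ccf(0.5, 1, 2), 1.0)
  expect_equal(compute_ccf(0.25, 0.5, 2), 0.25 * (2 * 0.5 + 1) / 0.5)
  expect_equal(compute_ccf(0.25, 0.5, 2), 1.0)  # capped
  expect_equal(compute_ccf(0.25, 0.5, 2, cap = FALSE), 1.0)
  # literal printed form disagrees: truncal het mutation gets 0.25
  expect_equal(compute_ccf(0.5, 1, 2, literal = TRUE), 0.25)
  expect_error(compute_ccf(0.5, 0, 2), "purity")
  expect_warning(ccf0 <- compute_ccf(0.5, 0.5, 0), "cn_tumor")
  expect_true(is.na(ccf0))
})

test_that("CCF increases strictly with VAF before capping", {
  vaf <- seq(0, 1, by = 0.05)
  for (purity in c(0.3, 0.6, 1)) {
    for (cn in c(1, 2, 4)) {
      ccf <- compute_ccf(vaf, purity, cn, cap = FALSE)
      expect_true(all(diff(ccf) > 0))
    }
  }
})

test_that("clonality labels, illusions and SNV-ITH follow the presence rule", {
  pres <- rbind(matrix(TRUE, 6, 3),
                cbind(rep(TRUE, 4), matrix(FALSE, 4, 2)))
  ccf <- matrix(0.5, 10, 3)
  ccf[7:10, 1] <- 0.95
  cl <- classify_clonality(pres, ccf)
  expect_equal(cl$label, c(rep("clonal", 6), rep("subclonal", 4)))
  expect_equal(cl$snv_ith, 0.4)
  expect_equal(sum(cl$illusion), 4)
  # absent regions do not contribute illusion evidence
  ccf2 <- matrix(0.5, 10, 3)
  ccf2[7:10, 2] <- 0.95  # high CCF only where the mutation is absent
  expect_equal(sum(classify_clonality(pres, ccf2)$illusion), 0)
  expect_error(classify_clonality(pres[, 1, drop = FALSE], ccf[, 1, drop = FALSE]),
               "single-region")
})

test_that("CCF clustering recovers planted clone structure", {
  set.seed(42)
  n <- 100; depth <- 200; purity <- c(0.8, 0.8)
  ccf_true <- rbind(matrix(rep(c(1, 1), each = n), n),
                    matrix(rep(c(0.4, 0.1), each = n), n))
  p <- t(t(ccf_true) * purity) / 2
  dep <- matrix(rpois(2 * n * 2, depth), 2 * n)
  alt <- matrix(rbinom(2 * n * 2, as.vector(dep), as.vector(p)), 2 * n)
  cl <- cluster_ccf(alt, dep, purity, seed = 1)
  expect_equal(cl$n_clusters, 2L)
  centers <- cl$prevalence[order(-rowMeans(cl$prevalence)), ]
  expect_lt(max(abs(centers - rbind(c(1, 1), c(0.4, 0.1)))), 0.05)
  # identical mutations land in the same cluster
  alt2 <- rbind(alt, alt[1, ]); dep2 <- rbind(dep, dep[1, ])
  cl2 <- cluster_ccf(alt2, dep2, purity, seed = 1)
  expect_equal(cl2$assignment[nrow(alt2)], cl2$assignment[1])
  # mutations all at CCF 1 give one cluster
  alt3 <- matrix(rbinom(40, 100, 0.4), 20)
  cl3 <- cluster_ccf(alt3, matrix(100, 20, 2), purity, seed = 1)
  expect_equal(cl3$n_clusters, 1L)
  expect_warning(cluster_ccf(alt[1:3, ], dep[1:3, ], purity), "fewer than 5")
})

test_that("clone tree construction enforces the cross and pigeonhole rules", {
  # B+C exceed A in region 1, so the chain A->B->C is the only option
  prev <- rbind(A = c(1, 1), B = c(0.7, 0.6), C = c(0.5, 0.5))
  tree <- build_clone_tree(prev)
  expect_equal(tree$parents, c(0L, 1L, 2L))
  expect_equal(tree$pattern, "linear")
  feas <- enumerate_feasible_trees(prev)
  expect_equal(length(feas), 1L)
  expect_equal(feas[[1]], tree$parents)
  # crossing siblings cannot nest: branched
  prev2 <- rbind(A = c(1, 1), B = c(0.6, 0.1), C = c(0.1, 0.6))
  tree2 <- build_clone_tree(prev2)
  expect_equal(tree2$parents, c(0L, 1L, 1L))
  expect_equal(tree2$pattern, "branched")
  # single cluster: root only
  expect_equal(build_clone_tree(matrix(1, 1, 2))$pattern, "linear")
  # no truncal cluster
  expect_error(build_clone_tree(rbind(c(1, 0.2), c(0.2, 1))), "truncal")
  # infeasible: crossing siblings that jointly exceed the root everywhere
  expect_error(build_clone_tree(rbind(c(1, 1), c(0.8, 0.3), c(0.3, 0.8))),
               "no feasible tree")
  expect_false(validate_clone_tree(prev, c(0L, 1L, 1L), eps = 0.05))
})

test_that("signature refit recovers planted exposures", {
  set.seed(7)
  sigs <- synthetic_signatures(3)
  ch_pure <- sample.int(96, 500, replace = TRUE, prob = sigs[, 2])
  fit <- fit_signatures(ch_pure, sigs)
  expect_gte(fit$exposures[2], 0.9)
  expect_true(all(fit$exposures >= 0))
  expect_equal(sum(fit$exposures), 1)
  mix <- 0.7 * sigs[, 1] + 0.3 * sigs[, 3]
  ch_mix <- sample.int(96, 1000, replace = TRUE, prob = mix)
  fit2 <- fit_signatures(ch_mix, sigs)
  expect_lt(abs(fit2$exposures[1] - 0.7), 0.1)
  expect_lt(abs(fit2$exposures[3] - 0.3), 0.1)
  # residual no worse than the uniform-exposure baseline
  unif <- rep(1 / 3, 3)
  spectrum <- tabulate(ch_mix, 96) / 1000
  expect_lte(fit2$residual, sqrt(sum((sigs %*% unif - spectrum)^2)))
  expect_warning(skip <- fit_signatures(ch_mix[1:14], sigs), "skipped")
  expect_true(skip$skipped)
  expect_error(fit_signatures(ch_mix, sigs[1:90, ]), "96 rows")
})
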