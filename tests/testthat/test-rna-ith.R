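test_that("expression filter keeps prevalent genes and log-transforms", {
  tpm <- matrix(0, 3, 10, dimnames = list(c("g1", "g2", "g3"), NULL))
  tpm[1, ] <- 5            # always expressed
  tpm[2, 1] <- 5           # 10% of samples only
  tpm[3, 1:2] <- 3         # exactly 20%
  out <- filter_normalize(tpm)
  expect_equal(rownames(out), c("g1", "g3"))
  expect_equal(unname(out["g1", 1]), log2(6))
  expect_equal(unname(out["g3", 3]), 0)
  expect_error(filter_normalize(tpm[0, ]), "empty")
  # constructed fixture: exactly the passing rows survive
  set.seed(3)
  tpm2 <- matrix(runif(100 * 8, 0, 0.5), 100, 8,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  tpm2[1:30, ] <- tpm2[1:30, ] + 2
  expect_equal(nrow(filter_normalize(tpm2)), 30)
})

test_that("heterogeneity quadrants recover planted gene classes", {
  px <- plant_quadrants()
  hs <- heterogeneity_scores(px$mat, px$patients)
  expect_gte(mean(hs$quadrant == px$truth), 0.9)
  # every retained gene gets exactly one quadrant and sizes add up
  expect_equal(sum(table(hs$quadrant)), nrow(px$mat))
  # constant gene: zero scores, class II
  mat2 <- px$mat; mat2[1, ] <- 3
  hs2 <- heterogeneity_scores(mat2, px$patients)
  expect_equal(hs2$intra[1], 0)
  expect_equal(hs2$inter[1], 0)
  expect_equal(hs2$quadrant[1], "II")
  # permuting region labels within patients leaves scores unchanged
  perm <- unlist(lapply(split(seq_along(px$patients), px$patients)[
    unique(px$patients)], sample))
  hs3 <- heterogeneity_scores(px$mat[, perm], px$patients[perm])
  expect_equal(hs3$intra, hs$intra)
  expect_equal(hs3$inter, hs$inter)
})

test_that("clustering concordance separates stable from noisy genes", {
  pat <- rep(paste0("P", 1:10), each = 4)
  # identical within patients, distinct between: perfect concordance
  mat <- matrix(rep(1:10, each = 4), 1, 40,
                dimnames = list("g1", NULL))
  expect_equal(clustering_concordance(mat, pat)$concordance, 1)
  # pure noise: concordance at its (negative) null level, far from 1
  set.seed(5)
  means <- replicate(100, {
    m <- matrix(rnorm(40), 1, 40, dimnames = list("g", NULL))
    clustering_concordance(m, pat)$concordance
  })
  expect_lt(mean(means), 0)
  expect_gt(mean(means), -0.6)
  # degenerate gene flagged with concordance 0
  flat <- matrix(1, 1, 40, dimnames = list("g1", NULL))
  cc <- clustering_concordance(flat, pat)
  expect_true(cc$degenerate)
  expect_equal(cc$concordance, 0)
})

test_that("planted Class IV genes outscore Class I on concordance", {
  px <- plant_quadrants(n_per = 30)
  hs <- heterogeneity_scores(px$mat, px$patients)
  cc <- clustering_concordance(px$mat, px$patients)
  iv <- cc$concordance[px$truth == "IV"]
  i <- cc$concordance[px$truth == "I"]
  expect_lt(stats::wilcox.test(iv, i, alternative = "greater")$p.value, 0.05)
})

test_that("patient RNA-ITH is zero for identical regions and robust to duplicates", {
  set.seed(6)
  base <- matrix(rnorm(200), 200, 1)
  same <- base[, c(1, 1, 1)]
  colnames(same) <- paste0("R", 1:3)
  expect_equal(patient_rna_ith(same)$score, 0)
  mat <- base %*% t(rep(1, 4)) + matrix(rnorm(800, 0, 0.5), 200, 4)
  colnames(mat) <- paste0("R", 1:4)
  s1 <- patient_rna_ith(mat)$score
  s2 <- patient_rna_ith(cbind(mat, mat[, 4]))$score  # duplicated region
  expect_lt(abs(s1 - s2), 0.05)
  expect_error(patient_rna_ith(mat[, 1, drop = FALSE]), ">= 2 regions")
  sat <- patient_rna_ith(mat)$saturation
  expect_equal(sat$r, 2:4)
})

test_that("dosage association finds planted copy-expression coupling", {
  set.seed(7)
  n <- 200
  pat <- rep(c("P1", "P2"), each = 2)
  base <- matrix(rnorm(n * 4, 5), n, 4, dimnames = list(sprintf("g%03d", 1:n), NULL))
  calls <- matrix("neutral", n, 4, dimnames = dimnames(base))
  calls[1:100, c(1, 3)] <- "gain"   # altered in one region per patient
  mat <- base + 0.8 * (calls == "gain")
  res <- dosage_association(mat, calls, pat)
  gain <- res$tests[res$tests$direction == "gain", ]
  expect_gt(gain$mean_delta, 0)
  expect_lt(gain$p, 0.05)
  # genes neutral everywhere contribute no pairs
  expect_false(any(res$shifts$gene %in% rownames(base)[101:200]))
  # null: no dosage effect, type-I error near alpha
  set.seed(8)
  rejections <- replicate(200, {
    m0 <- matrix(rnorm(50 * 4, 5), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
    c0 <- matrix("neutral", 50, 4, dimnames = dimnames(m0))
    c0[1:25, c(1, 3)] <- "gain"
    r <- dosage_association(m0, c0, pat)
    r$tests$p[r$tests$direction == "gain"] < 0.05
  })
  expect_lt(mean(rejections), 0.12)
})

test_that("gene copy classes split clonal from subclonal changes", {
  calls <- rbind(g1 = c("gain", "gain"), g2 = c("gain", "neutral"),
                 g3 = c("loss", "loss"), g4 = c("neutral", "loss"),
                 g5 = c("neutral", "neutral"))
  expect_equal(unname(gene_copy_class(calls)),
               c("clonal_gain", "subclonal_gain", "clonal_loss",
                 "subclonal_loss", "no_change"))
})

test_that("differential promoter methylation needs both Fisher p and delta", {
  # 30/60 vs 54/60 methylated: delta 0.4 and Fisher p < 0.05
  r <- differential_methylation_pair(30, 60, 54, 60)
  expect_true(r$differential)
  expect_equal(r$direction, -1)
  oracle <- stats::fisher.test(matrix(c(30, 30, 54, 6), 2))$p.value
  expect_lt(oracle, 0.05)
  # delta 0.15: never differential regardless of counts
  expect_false(differential_methylation_pair(300, 1000, 450, 1000)$differential)
  # delta large but counts tiny: Fisher not significant
  expect_false(differential_methylation_pair(1, 3, 3, 3)$differential)
})

test_that("promoter methylation shifts expression; gene body does not", {
  set.seed(9)
  n <- 60
  genes <- sprintf("g%02d", 1:n)
  mat <- matrix(rnorm(n * 2, 5, 0.1), n, 2, dimnames = list(genes, c("R1", "R2")))
  mat[, 2] <- mat[, 2] - 1.5  # promoter-hyper region expresses lower
  meth <- do.call(rbind, lapply(genes, function(g) {
    rbind(
      data.frame(gene = g, element = "promoter", region = "R1",
                 pos = 1:3, meth_reads = 10, total_reads = 60),
      data.frame(gene = g, element = "promoter", region = "R2",
                 pos = 1:3, meth_reads = 50, total_reads = 60),
      data.frame(gene = g, element = "gene_body", region = "R1",
                 pos = 11:13, meth_reads = 30, total_reads = 60),
      data.frame(gene = g, element = "gene_body", region = "R2",
                 pos = 11:13, meth_reads = 30, total_reads = 60))
  }))
  res <- promoter_methylation_association(mat, meth)
  prom <- res$tests[res$tests$element == "promoter", ]
  expect_lt(prom$p, 0.001)
  expect_lt(prom$mean_delta, 0)  # hypermethylated region expresses less
  expect_false("gene_body" %in% res$pairs$element)
})
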