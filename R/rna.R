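#' Filter and normalize a TPM expression matrix
#'
#' Keeps genes with at least `min_tpm` TPM in at least `min_frac` of the
#' samples, then transforms to log2(TPM + 1).
#'
#' @param tpm genes x samples non-negative TPM matrix.
#' @param min_tpm expression threshold (default 1).
#' @param min_frac minimum fraction of samples above threshold
#'   (default 0.2).
#' @return log2-transformed matrix of retained genes.
#' @export
filter_normalize <- function(tpm, min_tpm = 1, min_frac = 0.2) {
  tpm <- as.matrix(tpm)
  if (nrow(tpm) == 0 || ncol(tpm) == 0) stop("empty expression matrix")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  keep <- rowMeans(tpm >= min_tpm) >= min_frac
  log2(tpm[keep, , drop = FALSE] + 1)
}

#' Per-gene intra- and intertumor heterogeneity scores and quadrants
#'
#' intra(g): mean over patients (with >= 2 regions) of the standard
#' deviation of g across that patient's regions. inter(g): standard
#' deviation across patients of the patient means. Genes fall into four
#' quadrants by comparison with the two score means: I = high intra / low
#' inter, II = low / low, III = high / high, IV = low intra / high inter
#' (the stable, patient-discriminating class).
#'
#' @param mat genes x samples log2 expression matrix.
#' @param patients patient label per column.
#' @return data.frame(gene, intra, inter, quadrant).
#' @export
heterogeneity_scores <- function(mat, patients) {
  patients <- as.character(patients)
  tab <- table(patients)
  usable <- names(tab)[tab >= 2]
  if (length(usable) < 2) stop("need >= 2 patients with >= 2 regions")
  if (length(usable) < length(tab)) {
    warning(length(tab) - length(usable),
            " single-region patient(s) excluded from the intra score")
  }
  sds <- sapply(usable, function(p) {
    apply(mat[, patients == p, drop = FALSE], 1, stats::sd)
  })
  intra <- rowMeans(sds)
  means <- sapply(unique(patients), function(p) {
    rowMeans(mat[, patients == p, drop = FALSE])
  })
  inter <- apply(means, 1, stats::sd)
  hi_intra <- intra > mean(intra)
  hi_inter <- inter > mean(inter)
  quadrant <- ifelse(hi_intra & !hi_inter, "I",
              ifelse(!hi_intra & !hi_inter, "II",
              ifelse(hi_intra & hi_inter, "III", "IV")))
  data.frame(gene = rownames(mat), intra = intra, inter = inter,
             quadrant = quadrant, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-gene clustering concordance
#'
#' The mean silhouette width of the patient partition computed on the
#' single-gene expression vector (Euclidean): close to 1 when regions
#' cluster perfectly by patient on this gene alone. Note the null is not
#' centered at 0: for many small patient groups the mean silhouette of an
#' uninformative gene is negative (about -0.4 for 10 patients of 4
#' regions), because the nearest of many other clusters is closer than
#' the own-cluster average by chance. Rankings and between-class
#' comparisons are unaffected. Degenerate genes (all values equal)
#' score 0.
#'
#' @param mat genes x samples log2 expression matrix.
#' @param patients patient label per column.
#' @return data.frame(gene, concordance, degenerate).
#' @export
clustering_concordance <- function(mat, patients) {
  cl <- as.integer(factor(patients))
  if (length(unique(cl)) < 2) stop("need >= 2 patients")
  conc <- apply(mat, 1, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    mean(cluster::silhouette(cl, stats::dist(x))[, "sil_width"])
  })
  data.frame(gene = rownames(mat), concordance = ifelse(is.na(conc), 0, conc),
             degenerate = is.na(conc), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Patient-level RNA heterogeneity with a region-count saturation curve
#'
#' RNA-ITH is the median over region pairs of (1 - Spearman correlation)
#' of the retained genes. The saturation curve reports, for every region
#' count r = 2..k, the mean score over region subsets of size r (all
#' subsets when there are at most `max_enumerate`, otherwise
#' `n_subsets` seeded random ones).
#'
#' @param mat genes x regions log2 expression matrix of one patient.
#' @param max_enumerate enumerate all subsets up to this many.
#' @param n_subsets random subsets drawn otherwise.
#' @param seed RNG seed for the subset draws.
#' @return list: `score`, `saturation` (data.frame r, mean_score).
#' @export
patient_rna_ith <- function(mat, max_enumerate = 20L, n_subsets = 100L,
                            seed = 1L) {
  k <- ncol(mat)
  if (k < 2) stop("RNA-ITH needs >= 2 regions")
  rho <- stats::cor(mat, method = "spearman")
  dvec <- 1 - rho[lower.tri(rho)]
  score_of <- function(idx) {
    sub <- 1 - rho[idx, idx][lower.tri(rho[idx, idx])]
    stats::median(sub)
  }
  set.seed(seed)
  saturation <- do.call(rbind, lapply(2:k, function(r) {
    n_all <- choose(k, r)
    subsets <- if (n_all <= max_enumerate) {
      utils::combn(k, r, simplify = FALSE)
    } else {
      lapply(seq_len(n_subsets), function(i) sort(sample.int(k, r)))
    }
    data.frame(r = r, mean_score = mean(vapply(subsets, score_of, 1)))
  }))
  list(score = stats::median(dvec), saturation = saturation)
}

#' Gene copy class within one patient
#'
#' "clonal_gain"/"clonal_loss" when every region carries the same
#' non-neutral direction, "subclonal_gain"/"subclonal_loss" when only a
#' subset does (majority direction on ties), otherwise "no_change".
#'
#' @param calls genes x regions character matrix of per-gene segment
#'   calls ("amp" counts as gain).
#' @return character vector per gene.
#' @export
gene_copy_class <- function(calls) {
  apply(calls, 1, function(cc) {
    g <- cc %in% c("gain", "amp")
    l <- cc == "loss"
    if (all(g)) return("clonal_gain")
    if (all(l)) return("clonal_loss")
    if (!any(g) && !any(l)) return("no_change")
    if (sum(g) >= sum(l) && any(g)) return("subclonal_gain")
    "subclonal_loss"
  })
}

#' Paired expression shift between copy-altered and copy-neutral regions
#'
#' For every gene and patient with at least one altered and one neutral
#' region, the shift is mean log2 expression over altered regions minus
#' mean over neutral regions, separately for gains and losses; each
#' direction is tested by a two-sided paired t-test (one-sample t on the
#' shifts). Optionally tests enrichment of the five per-patient copy
#' classes across the four heterogeneity quadrants by two-sided Fisher's
#' exact tests.
#'
#' @param mat genes x samples log2 expression matrix.
#' @param calls genes x samples character matrix of segment calls
#'   aligned with `mat`.
#' @param patients patient label per column.
#' @param quadrants optional named quadrant per gene for the enrichment.
#' @return list: `shifts` (gene, patient, direction, delta), `tests`
#'   (direction, n, mean_delta, t, p), `enrichment` (class, quadrant,
#'   odds_ratio, p, q; NULL unless quadrants given).
#' @export
dosage_association <- function(mat, calls, patients, quadrants = NULL) {
  patients <- as.character(patients)
  shifts <- list()
  class_obs <- list()
  for (p in unique(patients)) {
    idx <- which(patients == p)
    if (length(idx) < 2) next
    sub_e <- mat[, idx, drop = FALSE]
    sub_c <- calls[, idx, drop = FALSE]
    gaini <- sub_c == "gain" | sub_c == "amp"
    lossi <- sub_c == "loss"
    neutr <- sub_c == "neutral"
    for (dir in c("gain", "loss")) {
      alt <- if (dir == "gain") gaini else lossi
      has_pair <- rowSums(alt) > 0 & rowSums(neutr) > 0
      if (!any(has_pair)) next
      delta <- vapply(which(has_pair), function(g) {
        mean(sub_e[g, alt[g, ]]) - mean(sub_e[g, neutr[g, ]])
      }, 1)
      shifts[[length(shifts) + 1L]] <- data.frame(
        gene = rownames(mat)[has_pair], patient = p, direction = dir,
        delta = delta, row.names = NULL, stringsAsFactors = FALSE)
    }
    class_obs[[length(class_obs) + 1L]] <- data.frame(
      gene = rownames(mat), patient = p,
      class = gene_copy_class(sub_c), row.names = NULL,
      stringsAsFactors = FALSE)
  }
  shifts <- if (length(shifts)) do.call(rbind, shifts) else NULL
  tests <- NULL
  if (!is.null(shifts)) {
    tests <- do.call(rbind, lapply(unique(shifts$direction), function(dir) {
      d <- shifts$delta[shifts$direction == dir]
      tt <- if (length(d) >= 2 && stats::sd(d) > 0) stats::t.test(d) else NULL
      data.frame(direction = dir, n = length(d), mean_delta = mean(d),
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  enrichment <- NULL
  if (!is.null(quadrants) && length(class_obs)) {
    obs <- do.call(rbind, class_obs)
    obs$quadrant <- quadrants[obs$gene]
    enrichment <- class_quadrant_enrichment(obs)
  }
  list(shifts = shifts, tests = tests, enrichment = enrichment)
}

class_quadrant_enrichment <- function(obs) {
  obs <- obs[!is.na(obs$quadrant), ]
  out <- list()
  for (cl in unique(obs$class)) {
    for (qd in unique(obs$quadrant)) {
      tab <- table(factor(obs$class == cl, c(TRUE, FALSE)),
                   factor(obs$quadrant == qd, c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, quadrant = qd, odds_ratio = unname(ft$estimate),
        p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Differential promoter methylation between two regions
#'
#' A promoter (or other element) is differentially methylated between two
#' regions when at least one shared CpG has a two-sided Fisher's exact
#' p-value below `p_threshold` on its (methylated, unmethylated) counts
#' AND an absolute level difference of at least `diff_threshold`.
#'
#' @param meth1,total1,meth2,total2 per-CpG methylated and total read
#'   counts in the two regions (aligned vectors).
#' @param p_threshold Fisher significance level (default 0.05).
#' @param diff_threshold minimum absolute methylation difference
#'   (default 0.2).
#' @return list: `differential` (logical), `direction` (sign of region1
#'   minus region2 over qualifying CpGs; 0 if not differential).
#' @export
differential_methylation_pair <- function(meth1, total1, meth2, total2,
                                          p_threshold = 0.05,
                                          diff_threshold = 0.2) {
  ok <- total1 > 0 & total2 > 0
  hit <- logical(length(meth1))
  delta <- rep(0, length(meth1))
  for (i in which(ok)) {
    d <- meth1[i] / total1[i] - meth2[i] / total2[i]
    if (abs(d) < diff_threshold) next
    tab <- matrix(c(meth1[i], total1[i] - meth1[i],
                    meth2[i], total2[i] - meth2[i]), 2)
    if (stats::fisher.test(tab)$p.value < p_threshold) {
      hit[i] <- TRUE
      delta[i] <- d
    }
  }
  list(differential = any(hit),
       direction = if (any(hit)) sign(mean(delta[hit])) else 0)
}

#' Expression shift at differentially methylated elements
#'
#' For every gene and ordered pair of regions of one patient, tests the
#' gene's element (promoter, first exon, gene body) for differential
#' methylation with [differential_methylation_pair()]; when differential,
#' records the expression difference of the hypermethylated minus the
#' hypomethylated region. Each element stratum is summarized with a
#' two-sided paired t-test.
#'
#' @param mat genes x regions log2 expression matrix of one patient.
#' @param meth data.frame(gene, element, region, pos, meth_reads,
#'   total_reads): per-CpG counts of each gene's annotated elements.
#' @param p_threshold,diff_threshold passed through.
#' @return list: `pairs` (gene, element, region_hyper, region_hypo,
#'   delta_expr), `tests` (element, n, mean_delta, t, p).
#' @export
promoter_methylation_association <- function(mat, meth,
                                             p_threshold = 0.05,
                                             diff_threshold = 0.2) {
  regions <- colnames(mat)
  pairs <- list()
  for (g in intersect(unique(meth$gene), rownames(mat))) {
    mg <- meth[meth$gene == g, ]
    for (el in unique(mg$element)) {
      me <- mg[mg$element == el, ]
      for (i in seq_along(regions)) {
        for (j in seq_along(regions)) {
          if (i >= j) next
          m1 <- me[me$region == regions[i], ]
          m2 <- me[me$region == regions[j], ]
          common <- intersect(m1$pos, m2$pos)
          if (!length(common)) next
          m1 <- m1[match(common, m1$pos), ]
          m2 <- m2[match(common, m2$pos), ]
          res <- differential_methylation_pair(
            m1$meth_reads, m1$total_reads, m2$meth_reads, m2$total_reads,
            p_threshold, diff_threshold)
          if (!res$differential) next
          hyper <- if (res$direction >= 0) i else j
          hypo <- if (res$direction >= 0) j else i
          pairs[[length(pairs) + 1L]] <- data.frame(
            gene = g, element = el,
            region_hyper = regions[hyper], region_hypo = regions[hypo],
            delta_expr = mat[g, hyper] - mat[g, hypo],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- do.call(rbind, lapply(unique(pairs$element), function(el) {
      d <- pairs$delta_expr[pairs$element == el]
      tt <- if (length(d) >= 2 && stats::sd(d) > 0) stats::t.test(d) else NULL
      data.frame(element = el, n = length(d), mean_delta = mean(d),
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(pairs = pairs, tests = tests)
}
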