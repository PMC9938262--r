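#' Deconvolve the tumor methylation rate from bulk methylation
#'
#' Inverts the purity- and copy-weighted mixture of tumor and normal
#' methylation: m_t = (m_b * (rho*n_t + n_n*(1-rho)) - n_n*m_n*(1-rho)) /
#' (rho*n_t). Technical and biological noise can push the raw value out
#' of [0, 1]; it is clamped back by default.
#'
#' @param m_b observed bulk methylation rate.
#' @param m_n matched-normal methylation rate.
#' @param purity tumor purity rho in (0, 1].
#' @param n_t local total tumor copy number (>= 1; n_t = 0 is undefined
#'   and returns NA with a warning).
#' @param n_n normal copy number (default 2).
#' @param clamp clamp the result to [0, 1] (default TRUE).
#' @return deconvolved tumor methylation rate, vectorized.
#' @export
deconvolve_methylation <- function(m_b, m_n, purity, n_t, n_n = 2,
                                   clamp = TRUE) {
  if (any(purity <= 0)) stop("purity must be positive")
  bad <- n_t == 0
  if (any(bad, na.rm = TRUE)) {
    warning("n_t = 0: tumor methylation undefined, returning NA")
  }
  m_t <- (m_b * (purity * n_t + n_n * (1 - purity)) -
            n_n * m_n * (1 - purity)) / (purity * n_t)
  m_t[bad] <- NA_real_
  if (clamp) m_t <- pmin(pmax(m_t, 0), 1)
  m_t
}

#' Bin per-CpG methylation into fixed-width genomic bins
#'
#' The bin level is the unweighted mean of the per-CpG methylation levels
#' of covered CpGs; bins with fewer than `min_cpgs` covered CpGs are
#' dropped. Aggregated read counts per bin are kept for count-based
#' differential tests. Input is sorted internally; duplicate positions on
#' one chromosome are an error.
#'
#' @param cpgs data.frame(chrom, pos, meth_reads, total_reads) of one
#'   sample.
#' @param bin_size bin width in bp (3000 for genome-wide profiles, 1000
#'   for DMR analysis).
#' @param min_cpgs minimum covered CpGs per retained bin (default 3).
#' @return data.frame(bin_id, chrom, start, level, n_cpgs, meth_reads,
#'   total_reads); bin_id encodes chrom and 0-based bin start.
#' @export
bin_methylation <- function(cpgs, bin_size = 3000, min_cpgs = 3) {
  if (nrow(cpgs) == 0) {
    return(data.frame(bin_id = character(), chrom = character(),
                      start = integer(), level = numeric(),
                      n_cpgs = integer(), meth_reads = integer(),
                      total_reads = integer(), stringsAsFactors = FALSE))
  }
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  if (anyDuplicated(cpgs[, c("chrom", "pos")])) {
    stop("duplicate CpG positions in input")
  }
  covered <- cpgs$total_reads > 0
  cpgs <- cpgs[covered, , drop = FALSE]
  start <- (cpgs$pos %/% bin_size) * bin_size
  key <- paste0(cpgs$chrom, ":", start)
  level <- cpgs$meth_reads / cpgs$total_reads
  agg <- data.frame(
    bin_id = tapply(key, key, `[`, 1),
    chrom = tapply(cpgs$chrom, key, `[`, 1),
    start = as.integer(tapply(start, key, `[`, 1)),
    level = as.numeric(tapply(level, key, mean)),
    n_cpgs = as.integer(tapply(level, key, length)),
    meth_reads = as.integer(tapply(cpgs$meth_reads, key, sum)),
    total_reads = as.integer(tapply(cpgs$total_reads, key, sum)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  agg <- agg[agg$n_cpgs >= min_cpgs, , drop = FALSE]
  agg[order(agg$chrom, agg$start), , drop = FALSE]
}

#' Call differentially methylated regions between tumor and normal bins
#'
#' Per bin shared by both profiles, a two-proportion z-test on the
#' aggregated methylated/unmethylated read counts with BH-adjusted
#' q-values. Hyper: q < `q_threshold` and level difference >
#' `diff_threshold`; hypo: q < `q_threshold` and difference <
#' -`diff_threshold`. Optionally tests enrichment of DMRs in annotated
#' genomic elements by a two-sided Fisher's exact test.
#'
#' @param tumor,normal binned profiles from [bin_methylation()] (tumor
#'   counts aggregated over regions when multi-regional).
#' @param diff_threshold minimum absolute methylation difference
#'   (default 0.25).
#' @param q_threshold BH q-value cutoff (default 0.01).
#' @param annotations optional data.frame(bin_id, element).
#' @return list: `table` (bin_id, diff, p, q, status) and `enrichment`
#'   (element, odds_ratio, p, q; NULL without annotations).
#' @export
call_dmrs <- function(tumor, normal, diff_threshold = 0.25,
                      q_threshold = 0.01, annotations = NULL) {
  common <- intersect(tumor$bin_id, normal$bin_id)
  if (!length(common)) stop("tumor and normal share no covered bins")
  t <- tumor[match(common, tumor$bin_id), ]
  n <- normal[match(common, normal$bin_id), ]
  p1 <- t$meth_reads / t$total_reads
  p2 <- n$meth_reads / n$total_reads
  pooled <- (t$meth_reads + n$meth_reads) / (t$total_reads + n$total_reads)
  se <- sqrt(pooled * (1 - pooled) * (1 / t$total_reads + 1 / n$total_reads))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  diff <- t$level - n$level
  status <- rep("none", length(common))
  status[q < q_threshold & diff > diff_threshold] <- "hyper"
  status[q < q_threshold & diff < -diff_threshold] <- "hypo"
  table <- data.frame(bin_id = common, diff = diff, p = p, q = q,
                      status = status, stringsAsFactors = FALSE)
  enrichment <- NULL
  if (!is.null(annotations)) {
    enrichment <- element_enrichment(table$bin_id[table$status != "none"],
                                     table$bin_id, annotations)
  }
  list(table = table, enrichment = enrichment)
}

#' Fisher enrichment of a bin set within annotated elements
#'
#' @param hits bin ids of interest (e.g. DMRs or top variable bins).
#' @param universe all tested bin ids.
#' @param annotations data.frame(bin_id, element).
#' @return data.frame(element, odds_ratio, p, q).
#' @export
element_enrichment <- function(hits, universe, annotations) {
  elements <- unique(annotations$element)
  out <- lapply(elements, function(el) {
    in_el <- universe %in% annotations$bin_id[annotations$element == el]
    is_hit <- universe %in% hits
    tab <- table(factor(is_hit, c(TRUE, FALSE)), factor(in_el, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    data.frame(element = el, odds_ratio = unname(ft$estimate),
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Most variable methylation bins across tumor regions
#'
#' Ranks bins by the standard deviation of their levels across regions;
#' ties (including the all-zero-SD case of identical regions) are broken
#' by bin id so the ranking is stable.
#'
#' @param levels bins x regions matrix of bin methylation levels with
#'   rownames = bin ids.
#' @param k number of top bins (default 500; all bins, with a warning,
#'   if fewer exist).
#' @param annotations optional data.frame(bin_id, element) for enrichment
#'   of the top set.
#' @return list: `table` (bin_id, sd, rank, top) and `enrichment`.
#' @export
variable_bins <- function(levels, k = 500, annotations = NULL) {
  if (ncol(levels) < 2) stop("variable bins need >= 2 regions")
  sds <- apply(levels, 1, stats::sd)
  ord <- order(-sds, rownames(levels))
  if (k > length(sds)) {
    warning("k exceeds the number of bins; returning all ", length(sds))
    k <- length(sds)
  }
  table <- data.frame(bin_id = rownames(levels)[ord], sd = sds[ord],
                      rank = seq_along(ord),
                      top = seq_along(ord) <= k,
                      row.names = NULL, stringsAsFactors = FALSE)
  enrichment <- NULL
  if (!is.null(annotations)) {
    enrichment <- element_enrichment(table$bin_id[table$top],
                                     table$bin_id, annotations)
  }
  list(table = table, enrichment = enrichment)
}

#' Average pairwise intratumor heterogeneity (APITH)
#'
#' APITH = 2/(k(k-1)) * sum over region pairs of the Euclidean distance
#' between their feature profiles: the mean pairwise distance, which is
#' unbiased with respect to the number of regions sampled.
#'
#' @param profiles features x regions matrix (typically methylation
#'   levels of DMR bins).
#' @return mean pairwise Euclidean distance (a scalar).
#' @export
compute_apith <- function(profiles) {
  k <- ncol(profiles)
  if (k < 2) stop("APITH needs at least 2 regions")
  d <- stats::dist(t(profiles))
  mean(d)
}

#' Epiallele diversity metrics of 4-CpG loci
#'
#' With p the relative frequencies of the 16 phased methylation patterns
#' at a locus: Shannon entropy = -sum(p * log2 p) (bits, unnormalized),
#' epipolymorphism = 1 - sum(p^2), and the proportion of discordant
#' reads (PDR) = the fraction of reads that are neither fully methylated
#' nor fully unmethylated. Loci with fewer than `min_reads` total reads
#' are reported but flagged unanalyzed (NA metrics).
#'
#' @param counts loci x 16 matrix (or data.frame) of pattern counts with
#'   columns ordered c0000..c1111 as in [pattern_names()].
#' @param min_reads coverage threshold (default 60).
#' @return data.frame(n_reads, entropy, epipolymorphism, pdr, analyzed).
#' @export
epiallele_metrics <- function(counts, min_reads = 60) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative epiallele counts")
  n <- rowSums(counts)
  p <- counts / ifelse(n > 0, n, 1)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  entropy <- -rowSums(plogp)
  epipoly <- 1 - rowSums(p^2)
  concordant <- match(c("c0000", "c1111"), pattern_names())
  pdr <- 1 - (p[, concordant[1]] + p[, concordant[2]])
  analyzed <- n >= min_reads
  out <- data.frame(n_reads = n, entropy = entropy,
                    epipolymorphism = epipoly, pdr = pdr,
                    analyzed = analyzed)
  out[!analyzed, c("entropy", "epipolymorphism", "pdr")] <- NA_real_
  out
}

#' Compare epiallele metrics between copy-altered and neutral loci
#'
#' Two-sided Wilcoxon rank-sum test of each metric between loci lying on
#' copy-number-altered versus copy-neutral segments. Strata with a single
#' locus are flagged low-n; an empty stratum gives NA with a warning.
#'
#' @param metrics data.frame with columns entropy, epipolymorphism, pdr
#'   (from [epiallele_metrics()], analyzed loci only).
#' @param altered logical vector: locus lies on an altered segment.
#' @return data.frame(metric, n_altered, n_neutral, W, p, low_n).
#' @export
compare_scna_vs_neutral <- function(metrics, altered) {
  stopifnot(nrow(metrics) == length(altered))
  out <- lapply(c("entropy", "epipolymorphism", "pdr"), function(mname) {
    x <- metrics[[mname]][altered]
    y <- metrics[[mname]][!altered]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      warning("empty stratum for ", mname)
      return(data.frame(metric = mname, n_altered = length(x),
                        n_neutral = length(y), W = NA_real_, p = NA_real_,
                        low_n = TRUE, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(metric = mname, n_altered = length(x), n_neutral = length(y),
               W = unname(wt$statistic), p = wt$p.value,
               low_n = length(x) < 2 || length(y) < 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
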