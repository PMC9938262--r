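#' Expected log2 copy-number ratio of a segment
#'
#' log2((purity * cn_seg + (1 - purity) * cn_n) / ploidy): the tumor
#' segment copy number mixed with the normal contamination at its neutral
#' copy number, relative to the sample ploidy. A homozygous deletion at
#' purity 1 gives -Inf, floored at -10.
#'
#' @param purity tumor purity in (0, 1].
#' @param cn_seg tumor copy number of the segment.
#' @param cn_n copy number of the copy-neutral (normal) state, default 2.
#' @param ploidy sample ploidy (> 0).
#' @return log2 ratio, vectorized, floored at -10.
#' @export
expected_log2ratio <- function(purity, cn_seg, cn_n = 2, ploidy = 2) {
  if (any(ploidy <= 0)) stop("ploidy must be positive")
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  ratio <- log2((purity * cn_seg + (1 - purity) * cn_n) / ploidy)
  pmax(ratio, -10)
}

#' Call gain / loss / amplification from ploidy-normalized log2 ratios
#'
#' Thresholds on the sample-mean-ploidy-normalized log2 scale:
#' gain at log2(2.5/2), loss at log2(1.5/2), amplification at log2(4/2).
#' Amplified segments are a subset of gained segments ("amp" implies
#' gain).
#'
#' @param ratio numeric vector of normalized log2 ratios.
#' @return character vector in {"amp", "gain", "neutral", "loss"}.
#' @export
call_gain_loss <- function(ratio) {
  out <- rep("neutral", length(ratio))
  out[ratio >= log2(2.5 / 2)] <- "gain"
  out[ratio >= log2(4 / 2)] <- "amp"
  out[ratio <= log2(1.5 / 2)] <- "loss"
  out
}

#' Fraction of each chromosome arm altered per region
#'
#' @param seg_calls data.frame(region, chrom, start, end, call) with calls
#'   from [call_gain_loss()] ("amp" counts as gain).
#' @param arms data.frame(chrom, start, end, name) of arm intervals,
#'   0-based half-open.
#' @return data.frame(arm, region, frac_gain, frac_loss).
#' @export
arm_fractions <- function(seg_calls, arms) {
  regions <- unique(seg_calls$region)
  out <- list()
  for (a in seq_len(nrow(arms))) {
    arm_len <- arms$end[a] - arms$start[a]
    for (r in regions) {
      seg <- seg_calls[seg_calls$region == r & seg_calls$chrom == arms$chrom[a], , drop = FALSE]
      ov_start <- pmax(seg$start, arms$start[a])
      ov_end <- pmin(seg$end, arms$end[a])
      ov <- pmax(ov_end - ov_start, 0)
      gain <- sum(ov[seg$call %in% c("gain", "amp")])
      loss <- sum(ov[seg$call == "loss"])
      out[[length(out) + 1L]] <- data.frame(
        arm = arms$name[a], region = r,
        frac_gain = gain / arm_len, frac_loss = loss / arm_len,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Arm-level clonal / subclonal SCNA calls
#'
#' Clonal gain (loss): every region has at least 75% of the arm gained
#' (lost) and at least one region reaches 90%. Otherwise subclonal gain
#' (loss) when at least one region exceeds 75%. Clonal is evaluated before
#' subclonal. When both directions would qualify as subclonal, the
#' direction with the larger maximal fraction wins.
#'
#' @param seg_calls data.frame(region, chrom, start, end, call), or a
#'   precomputed [arm_fractions()] table via `fractions`.
#' @param arms arm definition table (chrom, start, end, name); required
#'   unless `fractions` is given. Segments on chromosomes missing from
#'   the arm table raise an error.
#' @param fractions optional precomputed arm-fraction table.
#' @return data.frame(arm, call) with call in {clonal_gain, clonal_loss,
#'   subclonal_gain, subclonal_loss, none}.
#' @export
call_arm_events <- function(seg_calls = NULL, arms = NULL, fractions = NULL) {
  if (is.null(fractions)) {
    missing_chrom <- setdiff(unique(seg_calls$chrom), unique(arms$chrom))
    if (length(missing_chrom)) {
      stop("chromosome(s) absent from the arm definitions: ",
           paste(missing_chrom, collapse = ", "))
    }
    fractions <- arm_fractions(seg_calls, arms)
  }
  arms_u <- unique(fractions$arm)
  call <- vapply(arms_u, function(a) {
    f <- fractions[fractions$arm == a, ]
    arm_call_from_fractions(f$frac_gain, f$frac_loss)
  }, character(1))
  data.frame(arm = arms_u, call = unname(call), stringsAsFactors = FALSE)
}

#' @rdname call_arm_events
#' @param frac_gain,frac_loss per-region altered fractions of one arm.
#' @export
arm_call_from_fractions <- function(frac_gain, frac_loss) {
  if (all(frac_gain >= 0.75) && any(frac_gain >= 0.90)) return("clonal_gain")
  if (all(frac_loss >= 0.75) && any(frac_loss >= 0.90)) return("clonal_loss")
  sub_gain <- any(frac_gain > 0.75)
  sub_loss <- any(frac_loss > 0.75)
  if (sub_gain && sub_loss) {
    return(if (max(frac_gain) >= max(frac_loss)) "subclonal_gain" else "subclonal_loss")
  }
  if (sub_gain) return("subclonal_gain")
  if (sub_loss) return("subclonal_loss")
  "none"
}

#' Weighted genome instability index and genome-doubling flag
#'
#' Per autosome, the fraction of covered length whose total copy number
#' differs from the baseline (the rounded sample ploidy); wGII is the
#' mean of this fraction over the autosomes. Chromosomes without any
#' covered length are excluded with a warning. The genome-doubling proxy
#' flag is ploidy >= 3.
#'
#' @param segments data.frame(chrom, start, end, major_cn, minor_cn) of
#'   one region.
#' @param ploidy sample ploidy.
#' @return list: `wgii`, `gd`, `per_chrom` (named fractions),
#'   `baseline`.
#' @export
compute_wgii <- function(segments, ploidy) {
  baseline <- round(ploidy)
  chroms <- paste0("chr", 1:22)
  per <- rep(NA_real_, 22)
  names(per) <- chroms
  total <- segments$major_cn + segments$minor_cn
  len <- segments$end - segments$start
  for (i in seq_along(chroms)) {
    idx <- segments$chrom == chroms[i]
    if (!any(idx) || sum(len[idx]) == 0) next
    per[i] <- sum(len[idx][total[idx] != baseline]) / sum(len[idx])
  }
  if (anyNA(per)) {
    warning(sum(is.na(per)), " autosome(s) without coverage excluded from wGII")
  }
  list(wgii = mean(per, na.rm = TRUE), gd = ploidy >= 3,
       per_chrom = per, baseline = baseline)
}

#' Clonal and subclonal SCNA fractions across regions
#'
#' Partitions each chromosome into the minimal intervals induced by all
#' regions' breakpoints; an interval is altered in a region when its total
#' copy number deviates from that region's baseline (rounded ploidy), with
#' the deviation sign as direction. An altered interval is clonal when all
#' regions share the same non-neutral direction, otherwise subclonal. The
#' subclonal SCNA fraction is subclonal altered length over total altered
#' length (NA when nothing is altered).
#'
#' @param segments data.frame(region, chrom, start, end, major_cn,
#'   minor_cn) for all regions of one patient.
#' @param ploidy named per-region ploidy vector.
#' @return list: `subclonal_fraction`, `clonal_len`, `subclonal_len`.
#' @export
scna_ith_proportion <- function(segments, ploidy) {
  regions <- unique(segments$region)
  if (length(regions) < 2) stop("subclonality of SCNA needs >= 2 regions")
  clonal_len <- 0
  subclonal_len <- 0
  for (ch in unique(segments$chrom)) {
    seg_c <- segments[segments$chrom == ch, ]
    bp <- sort(unique(c(seg_c$start, seg_c$end)))
    if (length(bp) < 2) next
    starts <- bp[-length(bp)]
    ends <- bp[-1]
    dir_mat <- matrix(NA_real_, length(starts), length(regions))
    for (j in seq_along(regions)) {
      s <- seg_c[seg_c$region == regions[j], ]
      base <- round(ploidy[[regions[j]]])
      idx <- vapply(starts, function(x) {
        w <- which(s$start <= x & x < s$end)
        if (length(w)) w[1] else NA_integer_
      }, 1L)
      tot <- (s$major_cn + s$minor_cn)[idx]
      dir_mat[, j] <- sign(tot - base)
    }
    altered <- rowSums(dir_mat != 0, na.rm = TRUE) > 0
    same <- apply(dir_mat, 1, function(d) {
      !anyNA(d) && all(d != 0) && length(unique(d)) == 1
    })
    ilen <- ends - starts
    clonal_len <- clonal_len + sum(ilen[altered & same])
    subclonal_len <- subclonal_len + sum(ilen[altered & !same])
  }
  total <- clonal_len + subclonal_len
  list(subclonal_fraction = if (total > 0) subclonal_len / total else NA_real_,
       clonal_len = clonal_len, subclonal_len = subclonal_len)
}

#' Detect mirrored subclonal allelic imbalance from phased SNP BAFs
#'
#' For every arm and region the haplotype-A allele fraction of phased
#' heterozygous SNPs (coverage >= `min_cov`) is tested against 0.5 by a
#' one-sample t-test; the direction is the sign of the mean deviation.
#' A mirrored event is reported when at least two regions have
#' significant (alpha) deviations of opposite sign and the SNPs span at
#' least `arm_span` of the arm. Arms with fewer than `min_snps` usable
#' SNPs are skipped with a warning.
#'
#' @param baf data.frame(chrom, pos, region, ref_reads, alt_reads,
#'   haplotype) with haplotype in {"A", "B"} naming the haplotype of the
#'   ALT allele.
#' @param arms arm table (chrom, start, end, name).
#' @param min_cov minimum SNP coverage (default 10).
#' @param min_snps minimum SNPs per arm (default 10).
#' @param alpha per arm-region significance level (default 0.01).
#' @param arm_span minimum fraction of the arm the SNPs must span.
#' @return data.frame of events: arm, regions_up, regions_down, n_snps
#'   (zero rows when none).
#' @export
detect_msai <- function(baf, arms, min_cov = 10, min_snps = 10,
                        alpha = 0.01, arm_span = 0.75) {
  depth <- baf$ref_reads + baf$alt_reads
  baf <- baf[depth >= min_cov, , drop = FALSE]
  depth <- baf$ref_reads + baf$alt_reads
  fA <- ifelse(baf$haplotype == "A",
               baf$alt_reads / depth, baf$ref_reads / depth)
  events <- list()
  for (a in seq_len(nrow(arms))) {
    on_arm <- baf$chrom == arms$chrom[a] &
      baf$pos >= arms$start[a] & baf$pos < arms$end[a]
    if (!any(on_arm)) next
    regions <- unique(baf$region[on_arm])
    n_per_region <- table(baf$region[on_arm])
    if (any(n_per_region < min_snps)) {
      warning("arm ", arms$name[a], ": fewer than ", min_snps,
              " SNPs in some region; arm skipped")
      next
    }
    span <- (max(baf$pos[on_arm]) - min(baf$pos[on_arm])) /
      (arms$end[a] - arms$start[a])
    if (span < arm_span) next
    dir <- vapply(regions, function(r) {
      x <- fA[on_arm & baf$region == r]
      if (stats::sd(x) == 0) return(0)
      tt <- stats::t.test(x, mu = 0.5)
      if (tt$p.value < alpha) sign(mean(x) - 0.5) else 0
    }, numeric(1))
    if (any(dir > 0) && any(dir < 0)) {
      events[[length(events) + 1L]] <- data.frame(
        arm = arms$name[a],
        regions_up = paste(regions[dir > 0], collapse = ","),
        regions_down = paste(regions[dir < 0], collapse = ","),
        n_snps = sum(on_arm),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) {
    return(data.frame(arm = character(), regions_up = character(),
                      regions_down = character(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, events)
}
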