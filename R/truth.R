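#' Build the ground truth of a synthetic multi-region cohort
#'
#' Draws, for every patient, a clone tree with per-region cancer-cell
#' prevalences that satisfy the two phylogenetic feasibility rules used
#' throughout the pipeline: the *cross rule* (a descendant clone never
#' exceeds its ancestor's prevalence in any region) and the *pigeonhole
#' constraint* (sibling subtrees cannot jointly exceed their parent's
#' prevalence in any region). On top of the trees it lays out mutations,
#' allele-specific arm copy numbers (with optional genome doubling and one
#' planted mirrored allelic-imbalance arm per selected patient), planted
#' DMR bins, epiallele disorder levels, gene dosage classes, immune
#' infiltration states and HLA-LOH events.
#'
#' Prevalence allocation walks the tree top-down; in each region a parent
#' either hands its full prevalence to a single child (regional fixation,
#' the source of "clonal illusion" mutations) or splits a sub-unity share
#' among its children. Allocated prevalences are floored at 0.15 (below
#' that a clone is absent from the region) and capped at 0.8 unless fixed,
#' so true prevalences fall in {0} U [0.15, 0.8] U {1}.
#'
#' When `n_patients >= 4` (and the clone range permits >= 3 clones) the
#' first patient is forced to a linear chain and the second to a branched
#' topology so both evolution patterns are always represented.
#'
#' @param config a [sim_config()] object.
#' @return object of class "mrith_truth".
#' @export
build_truth <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  genome <- config$genome
  arms <- arm_ids(genome)

  bins <- layout_bins(genome, config$n_cpg_bins)
  dmr_truth <- plant_dmrs(bins, config)
  loci <- layout_epiallele_loci(genome, config)
  genes <- layout_genes(genome, bins, config)
  sigs <- synthetic_signatures(3L)

  force_linear <- config$n_patients >= 4 && max(config$n_clones) >= 3
  patients <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    k_regions <- sample_range(config$regions_per_patient)
    n_clones <- sample_range(config$n_clones)
    topology <- "random"
    if (force_linear && p == 1L) topology <- "linear"
    if (force_linear && p == 2L) {
      topology <- "branched"
      n_clones <- max(n_clones, 3L)
    }
    parents <- draw_parents(n_clones, topology)
    alloc <- allocate_prevalence(parents, k_regions)
    parents <- alloc$parents
    prev <- alloc$prevalence
    regions <- paste0("R", seq_len(k_regions))
    colnames(prev) <- regions

    purity <- stats::runif(k_regions, config$purity[1], config$purity[2])
    names(purity) <- regions

    gd <- stats::runif(1) < config$gd_fraction
    seg <- draw_arm_copies(arms, regions, gd, config)
    if (stats::runif(1) < config$msai_fraction && k_regions >= 2) {
      seg <- plant_msai(seg, arms, regions)
    }
    ploidy <- arm_weighted_ploidy(seg, genome)

    muts <- draw_mutations(parents, prev, genome, sigs, config)
    regional_dmr <- draw_regional_dmr(dmr_truth, regions)
    infiltration <- draw_infiltration(regions, config)
    hla <- list(alleles = c("HLA-A*01", "HLA-A*02", "HLA-B*01", "HLA-B*02"),
                lost = matrix(FALSE, 4L, k_regions,
                              dimnames = list(NULL, regions)),
                timing = "none")

    patients[[p]] <- list(
      id = sprintf("P%02d", p),
      regions = regions,
      purity = purity,
      ploidy = ploidy,
      parents = parents,
      prevalence = prev,
      mutations = muts,
      cnA = seg$cnA,
      cnB = seg$cnB,
      gd = gd,
      msai = seg$msai,
      regional_dmr = regional_dmr,
      infiltration = infiltration,
      hla = hla
    )
  }

  patients <- assign_hla_loh(patients, config)
  truth <- list(
    config = config,
    genome = genome,
    bins = bins,
    dmr_truth = dmr_truth,
    epiallele_loci = loci,
    genes = genes,
    signature_matrix = sigs,
    clonal_sig_weights = c(0.7, 0.3, 0),
    subclonal_sig_weights = c(0.2, 0.3, 0.5),
    patients = patients
  )
  class(truth) <- "mrith_truth"
  truth
}

sample_range <- function(rng) {
  rng <- as.integer(rng)
  if (length(rng) == 1L || rng[1] == rng[2]) return(rng[1])
  sample(seq(rng[1], rng[2]), 1L)
}

draw_parents <- function(n_clones, topology = c("random", "linear", "branched")) {
  topology <- match.arg(topology)
  if (n_clones == 1L) return(0L)
  parents <- integer(n_clones)
  parents[1] <- 0L
  for (j in 2:n_clones) {
    parents[j] <- switch(topology,
      linear = j - 1L,
      branched = if (j <= 3L) 1L else sample(seq_len(j - 1L), 1L),
      random = sample(seq_len(j - 1L), 1L)
    )
  }
  parents
}

#' Allocate per-region clone prevalences under the cross and pigeonhole rules
#'
#' Works top-down; a node present in fewer than two regions cannot host
#' crossing siblings, so its surplus children are re-parented to the root
#' (the returned parent vector reflects this). Returns the final parents
#' and the prevalence matrix.
#' @keywords internal
allocate_prevalence <- function(parents, k_regions,
                                p_fix = 0.2, floor = 0.15, cap = 0.8) {
  n <- length(parents)
  prev <- matrix(0, n, k_regions)
  prev[1, ] <- 1
  if (n == 1L) return(list(parents = parents, prevalence = prev))
  for (par in seq_len(n)) {
    kids <- which(parents == par)
    if (!length(kids)) next
    if (length(kids) >= 2 && sum(prev[par, ] > 0) < 2 && par != 1L) {
      move <- kids[-1]
      parents[move] <- 1L
      kids <- kids[1]
    }
    for (attempt in 1:200) {
      alloc <- matrix(0, length(kids), k_regions)
      for (r in seq_len(k_regions)) {
        pp <- prev[par, r]
        if (pp <= 0) next
        if (stats::runif(1) < p_fix) {
          alloc[sample.int(length(kids), 1L), r] <- pp
        } else {
          s <- stats::runif(1, 0.35, 0.8)
          w <- stats::rgamma(length(kids), 1)
          alloc[, r] <- pp * s * w / sum(w)
        }
      }
      fixed <- sweep(alloc, 2, prev[par, ], "==") & alloc > 0
      alloc[!fixed & alloc < floor] <- 0
      alloc[!fixed & alloc > cap] <- cap
      if (all(rowSums(alloc) > 0) && siblings_cross(alloc)) break
    }
    if (any(rowSums(alloc) == 0) || !siblings_cross(alloc)) {
      stop("infeasible config: could not place ", length(kids),
           " crossing sibling clones under the pigeonhole constraint")
    }
    prev[kids, ] <- alloc
  }
  list(parents = parents, prevalence = prev)
}

#' Every sibling pair occupies distinct regional niches
#'
#' TRUE when for each pair of rows neither dominates the other in every
#' region. Crossing siblings make the branched topology identifiable: no
#' chain arrangement of the siblings can satisfy the cross rule, so the
#' reconstructed evolution pattern is forced to match the truth.
#' @keywords internal
siblings_cross <- function(alloc) {
  k <- nrow(alloc)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (all(alloc[i, ] >= alloc[j, ]) || all(alloc[j, ] >= alloc[i, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

draw_arm_copies <- function(arms, regions, gd, config) {
  n_arms <- length(arms)
  k <- length(regions)
  base <- if (gd) 2L else 1L
  cnA <- matrix(base, n_arms, k, dimnames = list(arms, regions))
  cnB <- matrix(base, n_arms, k, dimnames = list(arms, regions))
  if (config$couple_gd_instability) {
    p_event <- if (gd) 0.35 else 0.15
    p_subclonal <- if (gd) 0.65 else 0.4
  } else {
    p_event <- 0.25
    p_subclonal <- 0.5
  }
  for (a in seq_len(n_arms)) {
    if (stats::runif(1) >= p_event) next
    gain <- stats::runif(1) < 0.5
    hapA <- stats::runif(1) < 0.5
    if (stats::runif(1) < p_subclonal && k >= 2) {
      n_in <- sample.int(k - 1L, 1L)
      idx <- sort(sample.int(k, n_in))
    } else {
      idx <- seq_len(k)
    }
    delta <- if (gain) {
      if (stats::runif(1) < 0.2) 2L else 1L  # occasional amplification
    } else {
      -1L
    }
    if (hapA) {
      cnA[a, idx] <- pmax(0L, cnA[a, idx] + delta)
    } else {
      cnB[a, idx] <- pmax(0L, cnB[a, idx] + delta)
    }
  }
  list(cnA = cnA, cnB = cnB, msai = NULL)
}

#' Overwrite one quiet arm with a mirrored gain: haplotype A gained in one
#' group of regions, haplotype B in the complementary group.
#' @keywords internal
plant_msai <- function(seg, arms, regions) {
  k <- length(regions)
  quiet <- which(apply(seg$cnA == seg$cnA[, 1], 1, all) &
                 apply(seg$cnB == seg$cnB[, 1], 1, all) &
                 seg$cnA[, 1] == seg$cnB[, 1])
  arm <- if (length(quiet)) quiet[sample.int(length(quiet), 1L)] else sample.int(length(arms), 1L)
  n_a <- sample.int(k - 1L, 1L)
  grp_a <- sort(sample.int(k, n_a))
  grp_b <- setdiff(seq_len(k), grp_a)
  seg$cnA[arm, ] <- seg$cnA[arm, 1]  # reset the arm to a flat state
  seg$cnB[arm, ] <- seg$cnB[arm, 1]
  seg$cnA[arm, grp_a] <- seg$cnA[arm, grp_a] + 1L
  seg$cnB[arm, grp_b] <- seg$cnB[arm, grp_b] + 1L
  seg$msai <- list(arm = arms[arm],
                   regions_a = regions[grp_a],
                   regions_b = regions[grp_b])
  seg
}

arm_weighted_ploidy <- function(seg, genome) {
  len <- genome$end - genome$start
  total <- seg$cnA + seg$cnB
  colSums(total * len) / sum(len)
}

draw_mutations <- function(parents, prev, genome, sigs, config) {
  n_clones <- length(parents)
  n_per <- pmax(5L, stats::rpois(n_clones, config$n_mutations))
  clone <- rep(seq_len(n_clones), n_per)
  n <- length(clone)
  genome_len <- sum(genome$end - genome$start)
  offs <- sort(sample.int(genome_len, n))
  cum <- cumsum(genome$end - genome$start)
  arm_idx <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = TRUE)
  pos <- genome$start[arm_idx] + (offs - 1L - c(0L, cum)[arm_idx])
  clonal <- apply(prev[clone, , drop = FALSE] > 0, 1, all)
  w_c <- sigs %*% config_sig_weights(TRUE)
  w_s <- sigs %*% config_sig_weights(FALSE)
  channel <- integer(n)
  if (any(clonal)) channel[clonal] <- sample.int(96L, sum(clonal), replace = TRUE, prob = w_c)
  if (any(!clonal)) channel[!clonal] <- sample.int(96L, sum(!clonal), replace = TRUE, prob = w_s)
  bases <- c("A", "C", "G", "T")
  data.frame(
    mut_id = sprintf("M%04d", seq_len(n)),
    chrom = genome$chrom[arm_idx],
    arm = arm_ids(genome)[arm_idx],
    pos = pos + 1L,  # 1-based in the variant table
    ref = sample(bases, n, replace = TRUE),
    alt = sample(bases, n, replace = TRUE),
    clone = clone,
    channel = channel,
    stringsAsFactors = FALSE
  )
}

config_sig_weights <- function(clonal) {
  if (clonal) c(0.7, 0.3, 0) else c(0.2, 0.3, 0.5)
}

#' Random 96-channel mutational signature profiles
#'
#' Sparse Dirichlet-style profiles used by the simulator and the signature
#' refit tests; each signature concentrates its mass on a random subset of
#' trinucleotide channels, as real signatures do.
#' @param n number of signatures.
#' @param concentration gamma shape of the active channels.
#' @return 96 x n column-stochastic matrix.
#' @export
synthetic_signatures <- function(n = 3L, concentration = 0.5) {
  sig <- matrix(0, 96L, n)
  for (j in seq_len(n)) {
    active <- sample.int(96L, 20L)
    w <- stats::rgamma(20L, concentration)
    sig[active, j] <- w / sum(w)
  }
  colnames(sig) <- paste0("S", seq_len(n))
  rownames(sig) <- sprintf("ch%02d", 1:96)
  sig
}

layout_bins <- function(genome, n_bins) {
  # spread 3-kb bins (5 CpGs each) evenly across the whole genome so that
  # bins -- and the genes anchored to them -- sample every arm
  len <- genome$end - genome$start
  genome_len <- sum(len)
  cum <- c(0L, cumsum(len))
  stride <- floor(genome_len / n_bins)
  offs <- (seq_len(n_bins) - 1L) * stride
  arm_idx <- findInterval(offs, cum, rightmost.closed = TRUE)
  start <- genome$start[arm_idx] + (offs - cum[arm_idx])
  over <- start + 3000L > genome$end[arm_idx]
  start[over] <- genome$end[arm_idx[over]] - 3000L
  bins <- data.frame(
    bin = seq_len(n_bins),
    chrom = genome$chrom[arm_idx],
    arm = arm_ids(genome)[arm_idx],
    start = as.integer(start),
    end = as.integer(start) + 3000L,
    stringsAsFactors = FALSE
  )
  bins$bin_id <- paste0(bins$chrom, ":", bins$start)
  bins
}

plant_dmrs <- function(bins, config) {
  n <- nrow(bins)
  normal <- ifelse(stats::runif(n) < 0.6, 0.85, 0.15) + stats::rnorm(n, 0, 0.03)
  normal <- pmin(pmax(normal, 0.02), 0.98)
  status <- rep("none", n)
  n_dmr <- round(config$dmr_fraction * n)
  if (n_dmr > 0) {
    lo <- which(normal <= 0.55)
    hi <- which(normal >= 0.45)
    n_hyper <- floor(n_dmr / 2)
    hyper <- sample(lo, min(n_hyper, length(lo)))
    hypo <- sample(setdiff(hi, hyper), min(n_dmr - length(hyper), length(setdiff(hi, hyper))))
    status[hyper] <- "hyper"
    status[hypo] <- "hypo"
  }
  tumor <- normal
  tumor[status == "hyper"] <- pmin(normal[status == "hyper"] + config$dmr_shift, 0.98)
  tumor[status == "hypo"] <- pmax(normal[status == "hypo"] - config$dmr_shift, 0.02)
  regional <- rep(FALSE, n)
  cand <- which(status == "none")
  regional[sample(cand, min(config$n_regional_dmr_bins, length(cand)))] <- TRUE
  data.frame(bins, status = status, m_normal = normal, m_tumor = tumor,
             regional = regional, stringsAsFactors = FALSE)
}

draw_regional_dmr <- function(dmr_truth, regions) {
  idx <- which(dmr_truth$regional)
  k <- length(regions)
  if (!length(idx) || k < 2) {
    return(data.frame(bin = integer(), high_regions = character()))
  }
  high <- vapply(idx, function(i) {
    n_hi <- sample.int(k - 1L, 1L)
    paste(sort(sample(regions, n_hi)), collapse = ",")
  }, character(1))
  data.frame(bin = idx, high_regions = high, stringsAsFactors = FALSE)
}

layout_epiallele_loci <- function(genome, config) {
  n <- config$n_epiallele_loci
  genome_len <- sum(genome$end - genome$start)
  offs <- sort(sample.int(genome_len - 200L, n))
  cum <- cumsum(genome$end - genome$start)
  arm_idx <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = TRUE)
  data.frame(
    locus = sprintf("L%04d", seq_len(n)),
    chrom = genome$chrom[arm_idx],
    arm = arm_ids(genome)[arm_idx],
    start = genome$start[arm_idx] + (offs - 1L - c(0L, cum)[arm_idx]),
    base_disorder = stats::runif(n, config$epiallele_disorder[1],
                                 config$epiallele_disorder[2]),
    stringsAsFactors = FALSE
  )
}

layout_genes <- function(genome, bins, config) {
  n <- config$n_genes
  bin_of <- rep_len(seq_len(nrow(bins)), n)  # every gene gets a promoter bin
  data.frame(
    gene = sprintf("G%04d", seq_len(n)),
    chrom = bins$chrom[bin_of],
    arm = bins$arm[bin_of],
    tss = bins$start[bin_of] + 1500L,
    promoter_bin = bin_of,
    stringsAsFactors = FALSE
  )
}

draw_infiltration <- function(regions, config) {
  k <- length(regions)
  kind <- sample(names(config$infiltration_probs), 1L,
                 prob = config$infiltration_probs)
  states <- switch(kind,
    high = rep("high", k),
    low = rep("low", k),
    het = {
      if (k < 2) rep(sample(c("high", "low"), 1L), k)
      else {
        n_hi <- sample.int(k - 1L, 1L)
        s <- rep("low", k)
        s[sample.int(k, n_hi)] <- "high"
        s
      }
    })
  names(states) <- regions
  states
}

assign_hla_loh <- function(patients, config) {
  n <- length(patients)
  n_clonal <- round(config$hla_loh_clonal_fraction * n)
  n_sub <- round(config$hla_loh_subclonal_fraction * n)
  picks <- sample.int(n, min(n, n_clonal + n_sub))
  for (i in seq_along(picks)) {
    p <- picks[i]
    allele <- sample.int(4L, 1L)
    k <- length(patients[[p]]$regions)
    if (i <= n_clonal || k < 2) {
      patients[[p]]$hla$lost[allele, ] <- TRUE
      patients[[p]]$hla$timing <- "clonal"
    } else {
      idx <- sort(sample.int(k, sample.int(k - 1L, 1L)))
      patients[[p]]$hla$lost[allele, idx] <- TRUE
      patients[[p]]$hla$timing <- "subclonal"
    }
  }
  patients
}

#' @export
print.mrith_truth <- function(x, ...) {
  cat("mrith cohort truth:", length(x$patients), "patients;",
      sum(vapply(x$patients, function(p) length(p$regions), 1L)), "regions;",
      sum(vapply(x$patients, function(p) nrow(p$mutations), 1L)), "mutations\n")
  invisible(x)
}
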