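#' Marker-based immune cell population scores
#'
#' The score of an immune population in a sample is the mean log2(TPM+1)
#' of that population's marker genes. Markers absent from the expression
#' matrix are excluded with a warning; populations with no present marker
#' are dropped with a warning.
#'
#' @param mat genes x samples log2(TPM+1) matrix.
#' @param registry named list population -> character vector of marker
#'   genes (see [default_marker_registry()]).
#' @return samples x populations score matrix.
#' @export
immune_scores <- function(mat, registry) {
  scores <- list()
  for (pop in names(registry)) {
    markers <- registry[[pop]]
    present <- markers[markers %in% rownames(mat)]
    if (!length(present)) {
      warning("population ", pop, " has no marker in the matrix; dropped")
      next
    }
    if (length(present) < length(markers)) {
      warning("population ", pop, ": ",
              length(markers) - length(present), " marker(s) missing")
    }
    scores[[pop]] <- colMeans(mat[present, , drop = FALSE])
  }
  do.call(cbind, scores)
}

#' Classify tumor regions into high / low immune infiltration
#'
#' Hierarchical clustering (Ward's D2 linkage on the Manhattan metric) of
#' the region x population score matrix, cut into two groups; the group
#' with the higher mean total-TIL score (overall mean score if that
#' population is absent) is labeled "high". Patients whose regions carry
#' both labels are "heterogeneous". Pairwise immune distance between
#' regions is the Euclidean distance of their score vectors.
#'
#' @param scores samples x populations matrix from [immune_scores()].
#' @param patients patient label per row.
#' @return list: `region_class` (named "high"/"low"), `patient_class`
#'   (named "high"/"low"/"heterogeneous"), `distance` (dist object).
#' @export
classify_til <- function(scores, patients) {
  if (nrow(scores) < 2) stop("TIL classification needs >= 2 regions")
  d <- stats::dist(scores, method = "manhattan")
  if (all(d == 0)) stop("all immune score vectors identical: no TIL split")
  hc <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  ref <- if ("total_TIL" %in% colnames(scores)) {
    scores[, "total_TIL"]
  } else {
    rowMeans(scores)
  }
  high_grp <- if (mean(ref[grp == 1]) >= mean(ref[grp == 2])) 1L else 2L
  region_class <- ifelse(grp == high_grp, "high", "low")
  names(region_class) <- rownames(scores)
  patient_class <- vapply(split(region_class, patients), function(lab) {
    if (all(lab == "high")) "high"
    else if (all(lab == "low")) "low"
    else "heterogeneous"
  }, character(1))
  list(region_class = region_class,
       patient_class = patient_class,
       distance = stats::dist(scores, method = "euclidean"))
}

#' Timing of HLA loss of heterozygosity per patient and allele
#'
#' "clonal" when the allele is lost in every region, "subclonal" when in
#' a proper non-empty subset, "none" otherwise. Conflicting duplicate
#' rows (same patient, region, allele with different loss calls) are an
#' error.
#'
#' @param hla_loh data.frame(patient, region, allele, lost).
#' @return data.frame(patient, allele, n_lost, n_regions, timing).
#' @export
classify_hla_loh_timing <- function(hla_loh) {
  key <- paste(hla_loh$patient, hla_loh$region, hla_loh$allele)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(dup, function(k) {
      length(unique(hla_loh$lost[key == k])) > 1
    }, logical(1))
    if (any(conflict)) stop("conflicting duplicate HLA-LOH rows")
    hla_loh <- hla_loh[!duplicated(key), ]
  }
  agg <- stats::aggregate(lost ~ patient + allele, hla_loh,
                          function(x) c(sum(x), length(x)))
  n_lost <- agg$lost[, 1]
  n_regions <- agg$lost[, 2]
  timing <- ifelse(n_lost == n_regions & n_lost > 0, "clonal",
            ifelse(n_lost > 0, "subclonal", "none"))
  data.frame(patient = agg$patient, allele = agg$allele,
             n_lost = n_lost, n_regions = n_regions, timing = timing,
             stringsAsFactors = FALSE)
}

#' Filter neoantigen candidates into putative and expressed sets
#'
#' Putative: mutant percentile rank <= `rank_threshold` and binding at
#' least as strong as the wild-type peptide (rank_mut <= rank_wt; lower
#' rank = stronger binding). HLA-LOH exclusion: a putative neoepitope
#' bound by a clonally lost allele is excluded; under subclonal LOH it is
#' excluded only when every clone carrying the neoepitope (the mutation's
#' clone and all its descendants in the clone tree) has lost the allele.
#' Expressed: at least 5 RNA-seq reads at the mutation position of which
#' at least 3 carry the mutant allele. Candidates with a missing rank are
#' skipped with a warning.
#'
#' @param candidates data.frame(patient, mut_id, peptide, hla_allele,
#'   rank_mut, rank_wt, rna_total_reads, rna_mut_reads, clone).
#' @param hla_timing output of [classify_hla_loh_timing()] (optional).
#' @param clone_loss optional data.frame(patient, allele, clone, lost)
#'   giving clone-level allele loss for subclonal-LOH exclusions; without
#'   it subclonal LOH never excludes.
#' @param parents optional named list patient -> parent vector of the
#'   clone tree (for the descendant closure).
#' @param clonality optional data.frame(patient, mut_id, label) used for
#'   the per-patient heterogeneity fraction.
#' @param rank_threshold percentile rank cutoff (default 2).
#' @return list: `table` (candidates + putative / excluded_loh /
#'   expressed flags), `summary` per patient (n_putative, n_excluded_loh,
#'   n_expressed, het_fraction).
#' @export
filter_neoantigens <- function(candidates, hla_timing = NULL,
                               clone_loss = NULL, parents = NULL,
                               clonality = NULL, rank_threshold = 2) {
  cand <- candidates
  missing_rank <- is.na(cand$rank_mut) | is.na(cand$rank_wt)
  if (any(missing_rank)) {
    warning(sum(missing_rank), " candidate(s) with missing rank skipped")
    cand <- cand[!missing_rank, , drop = FALSE]
  }
  putative <- cand$rank_mut <= rank_threshold & cand$rank_mut <= cand$rank_wt
  excluded <- rep(FALSE, nrow(cand))
  if (!is.null(hla_timing)) {
    tkey <- paste(hla_timing$patient, hla_timing$allele)
    timing <- hla_timing$timing[match(paste(cand$patient, cand$hla_allele), tkey)]
    timing[is.na(timing)] <- "none"
    excluded[putative & timing == "clonal"] <- TRUE
    sub_idx <- which(putative & timing == "subclonal")
    if (length(sub_idx) && !is.null(clone_loss)) {
      for (i in sub_idx) {
        pat <- cand$patient[i]
        clones <- clone_descendants(parents[[pat]], cand$clone[i])
        lost <- vapply(clones, function(cl) {
          hit <- clone_loss$patient == pat &
            clone_loss$allele == cand$hla_allele[i] & clone_loss$clone == cl
          any(hit) && all(clone_loss$lost[hit])
        }, logical(1))
        if (all(lost)) excluded[i] <- TRUE
      }
    }
  }
  expressed <- putative & !excluded &
    cand$rna_total_reads >= 5 & cand$rna_mut_reads >= 3
  tab <- data.frame(cand, putative = putative, excluded_loh = excluded,
                    expressed = expressed, stringsAsFactors = FALSE)
  het <- NULL
  if (!is.null(clonality)) {
    lab <- clonality$label[match(paste(tab$patient, tab$mut_id),
                                 paste(clonality$patient, clonality$mut_id))]
    tab$subclonal <- lab == "subclonal"
  }
  summary <- do.call(rbind, lapply(split(tab, tab$patient), function(s) {
    put <- s$putative & !s$excluded_loh
    data.frame(
      patient = s$patient[1],
      n_candidates = nrow(s),
      n_putative = sum(put),
      n_excluded_loh = sum(s$excluded_loh),
      n_expressed = sum(s$expressed),
      het_fraction = if (!is.null(s$subclonal) && sum(put) > 0) {
        mean(s$subclonal[put], na.rm = TRUE)
      } else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}

#' Clone plus all of its descendants in a parent vector
#' @keywords internal
clone_descendants <- function(parents, clone) {
  if (is.null(parents)) return(clone)
  out <- clone
  repeat {
    kids <- which(parents %in% out)
    new <- setdiff(kids, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  sort(out)
}
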