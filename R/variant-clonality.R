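#' Filter raw somatic variants with the high-quality triple rule
#'
#' A variant is kept when, in at least one tumor region, all three
#' conditions hold: (i) total depth above 10 in both the tumor region and
#' the matched normal; (ii) normal VAF below 0.02 with at most three
#' variant-supporting reads in the normal; (iii) tumor VAF above 0.05 with
#' more than five variant-supporting reads. Zero-depth sites simply fail
#' the depth condition.
#'
#' @param variants long table with columns patient, region, mut_id,
#'   t_alt, t_ref, n_alt, n_ref (plus any others, carried through).
#' @return list with `kept` (rows of passing variants, all regions) and
#'   `rejected` (patient, mut_id, reason).
#' @export
filter_variants <- function(variants) {
  need <- c("patient", "region", "mut_id", "t_alt", "t_ref", "n_alt", "n_ref")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(variants$n_alt) || anyNA(variants$n_ref)) {
    stop("matched-normal read counts are missing")
  }
  t_depth <- variants$t_alt + variants$t_ref
  n_depth <- variants$n_alt + variants$n_ref
  t_vaf <- ifelse(t_depth > 0, variants$t_alt / t_depth, 0)
  n_vaf <- ifelse(n_depth > 0, variants$n_alt / n_depth, 0)
  pass_depth <- t_depth > 10 & n_depth > 10
  pass_normal <- n_vaf < 0.02 & variants$n_alt <= 3
  pass_tumor <- t_vaf > 0.05 & variants$t_alt > 5
  pass_all <- pass_depth & pass_normal & pass_tumor

  key <- paste(variants$patient, variants$mut_id)
  keep_mut <- tapply(pass_all, key, any)
  keep_row <- keep_mut[key]
  rejected <- NULL
  if (any(!keep_row)) {
    rej <- variants[!keep_row, c("patient", "mut_id")]
    reason_row <- ifelse(!pass_depth[!keep_row], "depth",
                  ifelse(!pass_normal[!keep_row], "normal_support",
                         "tumor_support"))
    # per mutation: the first failing filter in the region passing the most
    n_pass <- (pass_depth + pass_normal + pass_tumor)[!keep_row]
    rkey <- paste(rej$patient, rej$mut_id)
    best <- tapply(seq_along(rkey), rkey, function(ii) ii[which.max(n_pass[ii])])
    rejected <- data.frame(rej[unlist(best), ],
                           reason = reason_row[unlist(best)],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  list(kept = variants[keep_row, , drop = FALSE], rejected = rejected)
}

#' Genotype mutation presence across regions
#'
#' A mutation is present in a region when its VAF exceeds 0.02 or more
#' than three reads support the variant allele (both strict).
#'
#' @param alt,depth mutation x region matrices of alt and total read
#'   counts.
#' @return logical matrix of the same shape.
#' @export
genotype_presence <- function(alt, depth) {
  vaf <- ifelse(depth > 0, alt / depth, 0)
  vaf > 0.02 | alt > 3
}

#' Cancer cell fraction of a mutation
#'
#' Default is the standard purity/copy mixture rearrangement:
#' CCF = VAF * (CN*rho + 2*(1-rho)) / (m*rho), capped to [0, 1].
#' `literal = TRUE` instead evaluates the alternative printed form
#' CCF = VAF * (1/rho) / (CN*rho + 2*(1-rho)), which fails the defining
#' property that a truncal heterozygous mutation at purity 1 and CN 2 has
#' CCF 1 (it gives 0.25); it is retained for comparison only.
#'
#' @param vaf variant allele frequency in [0, 1].
#' @param purity tumor purity rho in (0, 1].
#' @param cn_tumor local total copy number in the tumor.
#' @param multiplicity copies carrying the mutation (default 1).
#' @param literal evaluate the literal printed form instead.
#' @param cap cap the result to [0, 1] (default TRUE).
#' @return CCF, vectorized; NA with a warning where cn_tumor = 0 and
#'   vaf > 0 (inconsistent input).
#' @export
compute_ccf <- function(vaf, purity, cn_tumor, multiplicity = 1,
                        literal = FALSE, cap = TRUE) {
  if (any(purity <= 0)) stop("purity must be positive")
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stop("vaf must lie in [0, 1]")
  bad <- cn_tumor == 0 & vaf > 0
  if (any(bad, na.rm = TRUE)) {
    warning("cn_tumor = 0 with vaf > 0: flagged as NA (inconsistent)")
  }
  mix <- cn_tumor * purity + 2 * (1 - purity)
  ccf <- if (literal) {
    vaf * (1 / purity) / mix
  } else {
    vaf * mix / (multiplicity * purity)
  }
  ccf[bad] <- NA_real_
  if (cap) ccf <- pmin(pmax(ccf, 0), 1)
  ccf
}

#' Classify mutations as clonal or subclonal and flag clonal illusions
#'
#' Clonal = present in every region; otherwise subclonal. A subclonal
#' mutation is a *clonal illusion* when its CCF reaches
#' `illusion_ccf` (default 0.9) in at least one region where it is
#' present: sampled alone, that region would call it clonal. SNV-ITH is
#' the subclonal fraction.
#'
#' @param presence logical mutation x region matrix.
#' @param ccf numeric mutation x region matrix of CCFs (cluster-smoothed
#'   CCFs give the most stable illusion flags).
#' @param illusion_ccf CCF threshold operationalizing "appears clonal in
#'   a single sample"; exposed because no canonical cutoff exists.
#' @return list: `label` ("clonal"/"subclonal" per mutation), `illusion`
#'   (logical), `snv_ith` (subclonal proportion).
#' @export
classify_clonality <- function(presence, ccf, illusion_ccf = 0.9) {
  if (ncol(presence) < 2) {
    stop("clonality is undefined for a single-region patient")
  }
  clonal <- rowSums(presence) == ncol(presence)
  ccf_p <- ccf
  ccf_p[!presence] <- NA_real_
  high <- apply(ccf_p, 1, function(x) any(x >= illusion_ccf, na.rm = TRUE))
  illusion <- !clonal & high
  list(label = ifelse(clonal, "clonal", "subclonal"),
       illusion = illusion,
       snv_ith = mean(!clonal))
}

#' Cluster mutations into clones by a binomial-mixture EM on read counts
#'
#' Each cluster k has a per-region cellular prevalence theta[k, r]; a
#' mutation's alt count in region r is binomial with success probability
#' theta[k, r] * c[i, r], where c[i, r] = purity_r / (CN_ir * purity_r +
#' 2 (1 - purity_r)) maps prevalence to expected VAF (multiplicity 1).
#' EM with multiple kmeans/random restarts; the number of clusters is
#' chosen by BIC over 1..n_max components. Deterministic under `seed`.
#'
#' @param alt,depth mutation x region count matrices.
#' @param purity per-region purity vector.
#' @param cn mutation x region total copy number matrix (default 2).
#' @param n_max maximum number of clusters scanned.
#' @param n_restarts EM restarts per cluster count.
#' @param seed RNG seed.
#' @param criterion model-selection criterion: "aic" (default) or "bic".
#'   AIC is preferred here because the BIC penalty merges weakly
#'   separated clones (e.g. a regionally fixed clone next to a
#'   high-prevalence sibling), which destroys clonal-illusion detection;
#'   AIC trades a slight tendency to over-split (harmless downstream,
#'   since presence-based labels and the tree tolerance absorb near-
#'   duplicate clusters) for sensitivity to real subclones.
#' @return list: `assignment` (cluster per mutation), `prevalence`
#'   (cluster x region posterior-mean CCFs), `n_clusters`, `ic`
#'   (selected information criterion value), `loglik`.
#' @export
cluster_ccf <- function(alt, depth, purity, cn = NULL,
                        n_max = 10L, n_restarts = 20L, seed = 1L,
                        criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt); R <- ncol(alt)
  if (is.null(cn)) cn <- matrix(2, n, R)
  pur <- matrix(purity, n, R, byrow = TRUE)
  cfac <- pur / (cn * pur + 2 * (1 - pur))
  ccf_hat <- pmin(pmax(ifelse(depth > 0, alt / depth, 0) / cfac, 0), 1.2)
  if (n < 5) {
    warning("fewer than 5 mutations: single-cluster fallback")
    theta <- matrix(colSums(alt) / pmax(colSums(depth * cfac), 1e-9), 1, R)
    return(list(assignment = rep(1L, n),
                prevalence = pmin(pmax(theta, 0), 1),
                n_clusters = 1L, ic = NA_real_, loglik = NA_real_))
  }
  set.seed(seed)
  n_max <- min(n_max, n)
  best <- NULL
  fit_prev <- NULL
  worse_streak <- 0L
  for (K in seq_len(n_max)) {
    fit <- em_best_of(alt, depth, cfac, ccf_hat, K,
                      if (K == 1) 1L else n_restarts, fit_prev)
    fit_prev <- fit
    df <- K * R + K - 1
    ic <- -2 * fit$loglik + if (criterion == "bic") df * log(n) else 2 * df
    if (is.null(best) || ic < best$ic - 1e-8) {
      best <- c(fit, list(ic = ic, n_clusters = K))
      worse_streak <- 0L
    } else {
      # the criterion is unimodal in K in practice; stop after two
      # consecutive non-improvements
      worse_streak <- worse_streak + 1L
      if (worse_streak >= 2L) break
    }
  }
  gamma <- best$gamma
  list(assignment = max.col(gamma, ties.method = "first"),
       prevalence = pmin(pmax(best$theta, 0), 1),
       n_clusters = best$n_clusters, ic = best$ic, loglik = best$loglik)
}

em_best_of <- function(alt, depth, cfac, ccf_hat, K, n_restarts,
                       fit_prev = NULL) {
  # short-run strategy: structured inits (kmeans, hclust cut, splits of
  # the previous K's clusters) plus random restarts each get a few EM
  # iterations; only the best short run is polished to convergence
  n <- nrow(alt)
  if (K == 1) {
    return(em_binmix(alt, depth, cfac,
                     matrix(pmin(pmax(colMeans(ccf_hat), 1e-3), 1), 1),
                     max_iter = 300L))
  }
  inits <- list()
  km <- suppressWarnings(stats::kmeans(ccf_hat, centers = K, nstart = 10))
  inits[[1]] <- pmin(pmax(km$centers, 1e-3), 1)
  hcl <- stats::cutree(stats::hclust(stats::dist(ccf_hat), "ward.D2"), K)
  inits[[2]] <- do.call(rbind, lapply(split(seq_len(n), hcl), function(ii) {
    pmin(pmax(colMeans(ccf_hat[ii, , drop = FALSE]), 1e-3), 1)
  }))
  if (!is.null(fit_prev) && nrow(fit_prev$theta) == K - 1) {
    assign_prev <- max.col(fit_prev$gamma, ties.method = "first")
    for (j in seq_len(K - 1)) {
      ii <- which(assign_prev == j)
      if (length(ii) < 4) next
      lo <- apply(ccf_hat[ii, , drop = FALSE], 2, stats::quantile, 0.25)
      hi <- apply(ccf_hat[ii, , drop = FALSE], 2, stats::quantile, 0.75)
      inits[[length(inits) + 1L]] <-
        pmin(pmax(rbind(fit_prev$theta[-j, , drop = FALSE], lo, hi), 1e-3), 1)
    }
  }
  while (length(inits) < n_restarts) {
    inits[[length(inits) + 1L]] <- pmin(pmax(
      ccf_hat[sample.int(n, K), , drop = FALSE] + 1e-3, 1e-3), 1)
  }
  best <- NULL
  for (theta0 in inits) {
    fit <- em_binmix(alt, depth, cfac, theta0, max_iter = 25L)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  em_binmix(alt, depth, cfac, best$theta, max_iter = 300L)
}

em_binmix <- function(alt, depth, cfac, theta, max_iter = 200L, tol = 1e-6) {
  K <- nrow(theta); n <- nrow(alt)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  lchoose_const <- sum(lchoose(depth, alt))
  for (it in seq_len(max_iter)) {
    logl <- matrix(0, n, K)
    for (k in seq_len(K)) {
      p <- pmin(pmax(cfac * matrix(theta[k, ], n, ncol(cfac), byrow = TRUE),
                     1e-6), 1 - 1e-6)
      logl[, k] <- rowSums(alt * log(p) + (depth - alt) * log1p(-p)) + log(pi_k[k])
    }
    m <- apply(logl, 1, max)
    gamma <- exp(logl - m)
    rs <- rowSums(gamma)
    gamma <- gamma / rs
    ll <- sum(m + log(rs)) + lchoose_const
    # M-step
    for (k in seq_len(K)) {
      num <- colSums(gamma[, k] * alt)
      den <- colSums(gamma[, k] * depth * cfac)
      theta[k, ] <- pmin(pmax(num / pmax(den, 1e-9), 1e-4), 1)
    }
    pi_k <- pmax(colMeans(gamma), 1e-9)
    pi_k <- pi_k / sum(pi_k)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(theta = theta, pi = pi_k, gamma = gamma, loglik = ll)
}

#' Build a clone tree from cluster prevalences
#'
#' Attaches every cluster below the truncal cluster so that, within
#' tolerance `eps`, (a) the cross rule holds: a child's prevalence never
#' exceeds its parent's in any region; and (b) the pigeonhole constraint
#' holds: the prevalences of a parent's children sum to at most the
#' parent's in every region. When several parents are feasible the one
#' with the smallest mean prevalence is chosen (deepest nesting),
#' making the tree deterministic. The evolution pattern is "linear" when
#' the tree is a single chain, otherwise "branched".
#'
#' @param prevalence cluster x region prevalence matrix.
#' @param eps feasibility tolerance on prevalence comparisons.
#' @return list: `parents` (0 for the root), `root`, `pattern`.
#' @export
build_clone_tree <- function(prevalence, eps = 0.05) {
  prevalence <- as.matrix(prevalence)
  K <- nrow(prevalence)
  root <- which.max(rowMeans(prevalence))
  if (!all(apply(prevalence, 2, function(col) all(col <= col[root] + eps)))) {
    stop("no truncal cluster: no cluster dominates every region")
  }
  parents <- integer(K)
  parents[root] <- 0L
  if (K == 1) {
    return(list(parents = parents, root = root, pattern = "linear"))
  }
  order_rest <- setdiff(order(rowMeans(prevalence), decreasing = TRUE), root)
  placed <- root
  child_sum <- matrix(0, K, ncol(prevalence))
  for (k in order_rest) {
    feas <- placed[vapply(placed, function(par) {
      all(prevalence[k, ] <= prevalence[par, ] + eps) &&
        all(child_sum[par, ] + prevalence[k, ] <= prevalence[par, ] + eps)
    }, logical(1))]
    if (!length(feas)) {
      stop("no feasible tree: cluster ", k, " violates the cross rule or ",
           "pigeonhole constraint under every candidate parent")
    }
    par <- feas[which.min(rowMeans(prevalence)[feas])]
    parents[k] <- par
    child_sum[par, ] <- child_sum[par, ] + prevalence[k, ]
    placed <- c(placed, k)
  }
  n_children <- tabulate(parents[parents > 0], nbins = K)
  pattern <- if (all(n_children <= 1)) "linear" else "branched"
  list(parents = parents, root = root, pattern = pattern)
}

#' Exhaustive feasibility check of a clone tree
#'
#' Independent brute-force validator: walks every parent-child pair for
#' the cross rule and every parent for the pigeonhole constraint.
#'
#' @param prevalence cluster x region matrix.
#' @param parents parent vector (0 = root).
#' @param eps tolerance.
#' @return TRUE/FALSE.
#' @export
validate_clone_tree <- function(prevalence, parents, eps = 0.05) {
  prevalence <- as.matrix(prevalence)
  K <- nrow(prevalence)
  for (k in seq_len(K)) {
    par <- parents[k]
    if (par == 0) next
    if (any(prevalence[k, ] > prevalence[par, ] + eps)) return(FALSE)
  }
  for (par in seq_len(K)) {
    kids <- which(parents == par)
    if (!length(kids)) next
    s <- colSums(prevalence[kids, , drop = FALSE])
    if (any(s > prevalence[par, ] + eps)) return(FALSE)
  }
  # exactly one root, no cycles
  if (sum(parents == 0) != 1) return(FALSE)
  for (k in seq_len(K)) {
    seen <- integer(0); cur <- k
    while (cur != 0) {
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur); cur <- parents[cur]
    }
  }
  TRUE
}

#' Enumerate all feasible clone trees (small cluster counts)
#'
#' Exhaustively tries every parent assignment rooted at the truncal
#' cluster and keeps those passing [validate_clone_tree()]. Intended as a
#' test oracle for up to ~6 clusters.
#'
#' @param prevalence cluster x region matrix.
#' @param eps tolerance.
#' @return list of feasible parent vectors.
#' @export
enumerate_feasible_trees <- function(prevalence, eps = 0.05) {
  prevalence <- as.matrix(prevalence)
  K <- nrow(prevalence)
  root <- which.max(rowMeans(prevalence))
  others <- setdiff(seq_len(K), root)
  if (!length(others)) return(list(c(0L)))
  grid <- expand.grid(rep(list(seq_len(K)), length(others)))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    parents <- integer(K)
    parents[root] <- 0L
    parents[others] <- as.integer(grid[i, ])
    if (any(parents[others] == others)) next
    if (validate_clone_tree(prevalence, parents, eps)) {
      out[[length(out) + 1L]] <- parents
    }
  }
  out
}

#' Refit mutational-signature exposures by non-negative least squares
#'
#' Projects a 96-channel mutation spectrum onto a supplied signature
#' matrix (the package ships none) with non-negative exposures that are
#' normalized to sum to one. Sets with fewer than `min_mutations`
#' mutations are skipped.
#'
#' @param channels integer vector of 96-channel indices (one per
#'   mutation); with `as_counts = TRUE`, a length-96 count vector.
#' @param signatures 96 x S column-stochastic signature matrix.
#' @param min_mutations minimum set size to attempt a fit.
#' @param as_counts interpret `channels` as a 96-channel count vector.
#' @return list: `exposures` (length S, NA if skipped), `residual`
#'   (L2 reconstruction error), `n`, `skipped`.
#' @export
fit_signatures <- function(channels, signatures, min_mutations = 15L,
                           as_counts = FALSE) {
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96L) {
    stop("signature matrix must have 96 rows, got ", nrow(signatures))
  }
  counts <- if (as_counts) {
    stopifnot(length(channels) == 96L)
    as.numeric(channels)
  } else {
    tabulate(as.integer(channels), nbins = 96L)
  }
  n <- sum(counts)
  if (n < min_mutations) {
    warning("fewer than ", min_mutations, " mutations: signature fit skipped")
    return(list(exposures = rep(NA_real_, ncol(signatures)),
                residual = NA_real_, n = n, skipped = TRUE))
  }
  spectrum <- counts / n
  fit <- pracma::lsqnonneg(signatures, spectrum)
  x <- fit$x
  if (sum(x) > 0) x <- x / sum(x)
  names(x) <- colnames(signatures)
  list(exposures = x,
       residual = sqrt(sum((signatures %*% x - spectrum)^2)),
       n = n, skipped = FALSE)
}
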