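#' Cross-omics pairwise distances and intra- vs inter-patient comparison
#'
#' Computes, per omic profile, the Euclidean distance between all sample
#' pairs, labels every pair intra-patient or inter-patient, and compares
#' the two groups by a two-sided Wilcoxon rank-sum test. Each omic is
#' also clustered (complete linkage on its Euclidean distances, cut into
#' one group per patient) and summarized by cluster purity: the mean over
#' clusters of the largest within-cluster patient share.
#'
#' @param profiles named list of features x samples matrices (shared
#'   sample columns); NULL entries are skipped with a warning.
#' @param patients patient label per sample column.
#' @return data.frame per omic: n_intra, n_inter, median_intra,
#'   median_inter, W, p, cluster_purity; plus attribute "distances"
#'   (named list of dist objects).
#' @export
omic_distances <- function(profiles, patients) {
  patients <- as.character(patients)
  same <- outer(patients, patients, "==")
  intra_mask <- same[lower.tri(same)]
  dists <- list()
  rows <- list()
  for (omic in names(profiles)) {
    if (is.null(profiles[[omic]])) {
      warning("omic ", omic, " missing: skipped")
      next
    }
    d <- stats::dist(t(profiles[[omic]]))
    dists[[omic]] <- d
    dv <- as.vector(d)
    intra <- dv[intra_mask]
    inter <- dv[!intra_mask]
    wt <- if (length(intra) && length(inter)) {
      suppressWarnings(stats::wilcox.test(intra, inter))
    } else NULL
    k <- length(unique(patients))
    purity <- if (k >= 2 && k < length(patients)) {
      cl <- stats::cutree(stats::hclust(d, method = "complete"), k = k)
      mean(vapply(split(patients, cl), function(pp) {
        max(table(pp)) / length(pp)
      }, 1))
    } else NA_real_
    rows[[omic]] <- data.frame(
      omic = omic, n_intra = length(intra), n_inter = length(inter),
      median_intra = stats::median(intra), median_inter = stats::median(inter),
      W = if (is.null(wt)) NA_real_ else unname(wt$statistic),
      p = if (is.null(wt)) NA_real_ else wt$p.value,
      cluster_purity = purity, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "distances") <- dists
  out
}

#' Correlation report with optional partial correlation
#'
#' Spearman and Pearson coefficients with p-values; with `partial_on`,
#' both variables are residualized on the covariates by least squares and
#' the partial Pearson correlation of the residuals is reported (the
#' standard recipe for controlling e.g. tumor purity).
#'
#' @param x,y aligned numeric vectors (n >= 3 after NA removal).
#' @param partial_on optional numeric vector / matrix of covariates.
#' @return one-row data.frame: n, spearman_rho, spearman_p, pearson_r,
#'   pearson_p, partial_r, partial_p, degenerate.
#' @export
correlate <- function(x, y, partial_on = NULL) {
  ok <- stats::complete.cases(x, y, if (is.null(partial_on)) rep(0, length(x)) else partial_on)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(n = n, spearman_rho = NA_real_, spearman_p = NA_real_,
                      pearson_r = NA_real_, pearson_p = NA_real_,
                      partial_r = NA_real_, partial_p = NA_real_,
                      degenerate = TRUE))
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- stats::cor.test(x, y, method = "pearson")
  partial_r <- partial_p <- NA_real_
  if (!is.null(partial_on)) {
    z <- as.matrix(partial_on)[ok, , drop = FALSE]
    rx <- stats::resid(stats::lm(x ~ z))
    ry <- stats::resid(stats::lm(y ~ z))
    pt <- stats::cor.test(rx, ry, method = "pearson")
    partial_r <- unname(pt$estimate)
    partial_p <- pt$p.value
  }
  data.frame(n = n,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             partial_r = partial_r, partial_p = partial_p,
             degenerate = FALSE)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson's classical MDS (principal coordinates). For configurations
#' that embed exactly in `dims` dimensions the embedded pairwise
#' distances reproduce the input.
#'
#' @param d symmetric non-negative distance matrix (or dist object).
#' @param dims embedding dimension (default 2).
#' @return n x dims coordinate matrix.
#' @export
mds_embed <- function(d, dims = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (all(d == 0)) return(matrix(0, nrow(d), dims))  # coincident points
  coords <- stats::cmdscale(stats::as.dist(d), k = dims)
  if (ncol(coords) < dims) {
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  coords
}
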