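#' Synthetic mini-genome arm table
#'
#' Desk-scale genome used by the cohort simulator: 22 autosomes, each split
#' into a p and a q arm. Coordinates are 0-based half-open. Arm lengths are
#' scaled down (a few megabases per arm) so that simulated cohorts stay
#' small while keeping per-chromosome structure (needed for wGII, arm-level
#' SCNA calls and MSAI).
#'
#' @param arm_bp approximate arm length in bp; the q arm is made 1.5x the
#'   p arm to mimic the acrocentric tendency of real chromosomes.
#' @return data.frame with columns chrom, arm ("p"/"q"), start, end.
#' @export
default_genome <- function(arm_bp = 2e6) {
  chroms <- paste0("chr", 1:22)
  p_len <- as.integer(arm_bp)
  q_len <- as.integer(1.5 * arm_bp)
  do.call(rbind, lapply(chroms, function(ch) {
    data.frame(
      chrom = ch,
      arm = c("p", "q"),
      start = c(0L, p_len),
      end = c(p_len, p_len + q_len),
      stringsAsFactors = FALSE
    )
  }))
}

#' Arm identifiers ("chr1p", "chr1q", ...)
#' @param genome arm table as from [default_genome()]
#' @keywords internal
arm_ids <- function(genome) paste0(genome$chrom, genome$arm)

#' Look up the arm row covering a position
#' @keywords internal
locate_arm <- function(genome, chrom, pos) {
  idx <- which(genome$chrom == chrom & genome$start <= pos & pos < genome$end)
  if (length(idx) != 1L) stop("position ", chrom, ":", pos, " not covered by exactly one arm")
  idx
}
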