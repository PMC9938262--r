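#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits every input format the pipeline consumes: `variants.tsv`,
#' `variants.vcf` (minimal VCF 4.2 with one sample column per
#' patient-region), `segments.seg.tsv`, `purity_ploidy.tsv`,
#' `methylation.bedgraph.tsv`, `epialleles.tsv`, `expression.tpm.tsv`,
#' `snp_baf.tsv`, `neoantigen_candidates.tsv`, `hla_loh.tsv`, `meta.tsv`,
#' `arms.bed`, `markers.yaml`, `config.yaml` and `truth.json`.
#' Reading the directory back with [read_cohort()] reproduces the tables
#' exactly.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(cohort$variants, "variants.tsv")
  wt(cohort$segments, "segments.seg.tsv")
  wt(cohort$purity_ploidy, "purity_ploidy.tsv")
  wt(cohort$methylation, "methylation.bedgraph.tsv")
  wt(cohort$epialleles, "epialleles.tsv")
  wt(cohort$snp_baf, "snp_baf.tsv")
  wt(cohort$neoantigens, "neoantigen_candidates.tsv")
  wt(cohort$hla_loh, "hla_loh.tsv")
  wt(cohort$meta, "meta.tsv")
  expr <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  wt(expr, "expression.tpm.tsv")
  genome <- cohort$truth$genome
  arms_bed <- data.frame(chrom = genome$chrom, start = genome$start,
                         end = genome$end, name = arm_ids(genome))
  utils::write.table(arms_bed, file.path(out_dir, "arms.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(cohort$marker_registry, file.path(out_dir, "markers.yaml"))
  cfg <- cohort$config
  cfg$genome <- NULL  # arms.bed carries the genome
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  write_truth_json(cohort$truth, file.path(out_dir, "truth.json"))
  write_vcf(cohort$variants, file.path(out_dir, "variants.vcf"))
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory path.
#' @return list mirroring the rendered cohort tables plus `truth`
#'   (as a plain list), `marker_registry`, `config` and `arms`.
#' @export
read_cohort <- function(dir) {
  rd <- function(file, ...) {
    utils::read.table(file.path(dir, file), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
  }
  expr_df <- rd("expression.tpm.tsv")
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$gene
  arms <- utils::read.table(file.path(dir, "arms.bed"), sep = "\t",
                            col.names = c("chrom", "start", "end", "name"),
                            stringsAsFactors = FALSE)
  list(
    variants = rd("variants.tsv"),
    segments = rd("segments.seg.tsv"),
    purity_ploidy = rd("purity_ploidy.tsv"),
    methylation = rd("methylation.bedgraph.tsv"),
    epialleles = rd("epialleles.tsv"),
    snp_baf = rd("snp_baf.tsv"),
    neoantigens = rd("neoantigen_candidates.tsv"),
    hla_loh = rd("hla_loh.tsv"),
    meta = rd("meta.tsv"),
    expression = expression,
    marker_registry = yaml::read_yaml(file.path(dir, "markers.yaml")),
    config = yaml::read_yaml(file.path(dir, "config.yaml")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE),
    arms = arms
  )
}

write_truth_json <- function(truth, path) {
  slim <- list(
    seed = truth$config$seed,
    patients = lapply(truth$patients, function(p) list(
      id = p$id,
      regions = p$regions,
      purity = as.list(p$purity),
      ploidy = as.list(p$ploidy),
      parents = p$parents,
      prevalence = apply(p$prevalence, 1, as.list, simplify = FALSE),
      mutation_clone = stats::setNames(as.list(p$mutations$clone),
                                       p$mutations$mut_id),
      gd = p$gd,
      msai = p$msai,
      infiltration = as.list(p$infiltration),
      hla_timing = p$hla$timing
    )),
    dmr_status = stats::setNames(as.list(truth$dmr_truth$status),
                                 truth$dmr_truth$bin_id),
    epiallele_disorder = stats::setNames(
      as.list(truth$epiallele_loci$base_disorder),
      truth$epiallele_loci$locus)
  )
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Write a minimal multi-sample VCF 4.2 of the variant read counts
#'
#' One sample column per patient-region; FORMAT is `AD:DP` (ref,alt depth
#' and total depth). Sites of other patients are encoded as missing.
#' @param variants long variant table (patient, region, chrom, pos, ref,
#'   alt, t_alt, t_ref).
#' @param path output file.
#' @export
write_vcf <- function(variants, path) {
  variants$sample <- paste(variants$patient, variants$region, sep = "_")
  samples <- unique(variants$sample)
  key <- paste(variants$patient, variants$chrom, variants$pos,
               variants$ref, variants$alt, sep = "|")
  sites <- !duplicated(key)
  site_tab <- variants[sites, c("patient", "chrom", "pos", "ref", "alt", "mut_id")]
  gmat <- matrix("./.:.", nrow(site_tab), length(samples),
                 dimnames = list(NULL, samples))
  idx_site <- match(key, key[sites])
  idx_sample <- match(variants$sample, samples)
  gmat[cbind(idx_site, idx_sample)] <-
    paste0(variants$t_ref, ",", variants$t_alt, ":",
           variants$t_ref + variants$t_alt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mrith",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(site_tab$chrom, site_tab$pos, site_tab$mut_id, site_tab$ref,
                site_tab$alt, ".", "PASS",
                paste0("PATIENT=", site_tab$patient), "AD:DP",
                apply(gmat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-region read counts back from a [write_vcf()] file
#' @param path VCF file.
#' @return long data.frame (patient, region, mut_id, chrom, pos, ref, alt,
#'   t_alt, t_ref).
#' @export
read_vcf_counts <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(header, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  out <- list()
  for (f in fields) {
    patient <- sub("PATIENT=", "", f[8])
    for (s in seq_along(samples)) {
      g <- f[9 + s]
      if (g == "./.:.") next
      ad <- strsplit(strsplit(g, ":")[[1]][1], ",")[[1]]
      region <- sub(paste0(patient, "_"), "", samples[s])
      out[[length(out) + 1L]] <- data.frame(
        patient = patient, region = region, mut_id = f[3],
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
        t_alt = as.integer(ad[2]), t_ref = as.integer(ad[1]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
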