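Package: mrith
Title: Multi-Region Multi-Omics Intratumor Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for intratumor heterogeneity (ITH) in
    multi-region tumor sequencing cohorts spanning genome, methylome,
    transcriptome and immune microenvironment. Implements cancer cell
    fraction (CCF) estimation and variant clonality classification,
    clone-tree reconstruction under pigeonhole and cross-rule constraints,
    mutational-signature exposure refitting, allele-specific copy-number
    instability metrics (wGII, genome doubling, subclonal SCNA fraction)
    and mirrored subclonal allelic imbalance (MSAI) detection, purity- and
    copy-aware methylation deconvolution with differentially methylated
    region calling, epiallele diversity metrics (entropy, epipolymorphism,
    proportion of discordant reads) and average pairwise ITH (APITH),
    RNA heterogeneity quadrants with clustering concordance, marker-based
    immune infiltration scoring, and a neoantigen filtering cascade with
    HLA loss-of-heterozygosity exclusion. Ships a synthetic multi-region
    cohort generator with known ground truth so every stage is testable
    without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    cluster,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
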