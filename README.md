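# mrith — multi-region multi-omics intratumor heterogeneity

`mrith` is an R analysis pipeline for **intratumor heterogeneity (ITH)**
in cohorts where several spatially separated regions of each tumor were
profiled at multiple molecular layers — somatic variants, allele-specific
copy number, RRBS methylomes, RNA expression — together with the immune
microenvironment. It is aimed at cancer-genomics analysts who want the
standard multi-region ITH battery as plain, tested R functions rather
than a chain of external tools.

The pipeline covers:

* **Variant clonality** — high-quality variant filtering, per-region
  presence genotyping, cancer cell fractions
  `CCF = VAF·(n_T·ρ + 2(1−ρ))/(m·ρ)`, clonal/subclonal labels,
  clonal-illusion flags, binomial-mixture EM clone clustering, and clone
  trees under the pigeonhole and cross rules with an exhaustive
  feasibility oracle; non-negative least-squares refitting of
  mutational-signature exposures for clonal vs subclonal sets.
* **Copy-number instability** — ploidy-normalized log2 ratios with
  gain/loss/amplification thresholds at log2(2.5/2), log2(1.5/2),
  log2(4/2); arm-level clonal/subclonal events (75%/90% rules); wGII
  against the rounded sample ploidy; genome-doubling flag (ploidy ≥ 3);
  subclonal SCNA fraction over minimal breakpoint intervals; mirrored
  subclonal allelic imbalance (MSAI) from phased SNP BAFs.
* **Methylome ITH** — purity/copy-aware deconvolution
  `m_t = (m_b(ρ·n_t + n_n(1−ρ)) − n_n·m_n(1−ρ))/(ρ·n_t)`, fixed-width
  binning, DMR calling (q < 0.01, |Δ| > 0.25) with element enrichment,
  variable bins, APITH (mean pairwise distance between regions), and
  epiallele diversity: Shannon entropy, epipolymorphism `1 − Σp²`, and
  the proportion of discordant reads.
* **RNA ITH** — prevalence filtering and log2(TPM+1), per-gene
  intra/inter heterogeneity quadrants, clustering concordance, patient
  RNA-ITH with region-count saturation, and the association of
  expression with copy dosage and promoter methylation.
* **Immune & neoantigens** — marker-based immune scores, Ward-D2 /
  Manhattan TIL high/low classification with heterogeneous patients,
  HLA-LOH timing, and the neoantigen cascade (rank ≤ 2, at least
  wild-type affinity, HLA-LOH exclusion, RNA expression support).
* **Integration** — intra- vs inter-patient distances per omic, MDS,
  and a correlation battery with purity-partialled correlations.

Because the cohorts such analyses are built on are access-restricted,
the package includes a first-class **synthetic cohort generator**
(`sim_config()`, `simulate_cohort()`, `write_cohort()`) that emits every
input format with complete ground truth — clone trees with region-wise
prevalences, planted mirrored arms, planted DMRs, dosage and
promoter-methylation couplings, and two immune infiltration states — so
every stage is tested against known truth. See the methods vignette
(`vignettes/multiomics-ith-methods.Rmd`) for the models, parameter
defaults and their rationale.

## Worked example

```r
library(mrith)

co  <- simulate_cohort(sim_config(n_patients = 4, seed = 42))
res <- run_pipeline(co)
res$summary[, c("patient", "n_regions", "snv_ith", "evolution_pattern",
                "mean_wgii", "gd")]
```

```
 patient n_regions snv_ith evolution_pattern mean_wgii   gd
     P01         5   0.000            linear     0.173 TRUE
     P02         4   0.738          branched     0.298 TRUE
     P03         3   0.000            linear     0.306 TRUE
     P04         3   0.646          branched     0.242 TRUE
```

Per patient: `snv_ith` is the subclonal fraction of mutations (P01's
mutations are all shared by its five regions; 74% of P02's are private
to a subset), `evolution_pattern` is the clone-tree topology inferred
under the pigeonhole/cross-rule constraints, `mean_wgii` is the mean
weighted genome instability index across regions, and `gd` flags genome
doubling (ploidy ≥ 3). The same summary carries APITH (methylome),
RNA-ITH, TIL class and neoantigen counts per patient.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow — `01_simulate.R` writes the cohort directory,
`02_clonality.R` … `06_immune.R` each produce one stage's tables, and
`07_integrate.R` writes the cross-omics comparison and the per-patient
summary — all under `results/`:

```sh
Rscript analysis/01_simulate.R 1 results/cohort
Rscript analysis/02_clonality.R 1 results
...
Rscript analysis/07_integrate.R 1 results
```

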