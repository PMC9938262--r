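---
title: "Methods: multi-region multi-omics intratumor heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region multi-omics intratumor heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrith)
```

# Scope

`mrith` re-implements, as one tested pipeline, the analyses used to
dissect intratumor heterogeneity (ITH) in multi-region tumor sequencing
cohorts profiled at three molecular layers (exome, reduced-representation
bisulfite methylome, transcriptome) plus the immune microenvironment:
variant clonality and clone trees, copy-number instability and mirrored
allelic imbalance, methylome heterogeneity and epiallele diversity, RNA
heterogeneity quadrants, immune-infiltrate classification, and
neoantigen-evasion filtering. Because the patient-level data such studies
rest on is access-restricted, the package ships a synthetic cohort
generator with complete ground truth; every claim the pipeline makes is
tested against that truth.

# The cancer-cell-fraction model

A somatic mutation carried by a fraction CCF of the cancer cells of a
region with purity $\rho$, local tumor copy number $n_T$, and mutation
multiplicity $m$ has expected variant allele frequency

$$\mathrm{VAF} = \frac{\mathrm{CCF}\, m\, \rho}{n_T\,\rho + 2(1-\rho)},$$

so the estimator is
$\mathrm{CCF} = \mathrm{VAF}\,(n_T \rho + 2(1-\rho)) / (m\rho)$, capped to
$[0,1]$ (`compute_ccf()`). A published variant of this formula places the
copy-number mixture term in the denominator; under it a truncal
heterozygous mutation at purity 1 and $n_T=2$ would receive CCF 0.25,
contradicting the definition of clonality, so the standard rearrangement
is the default and the alternative is available behind
`literal = TRUE` for comparison. Multiplicity defaults to 1 — the common
convention when phasing information is absent — and the generator places
mutations on a single allele accordingly.

## Clone clustering

Mutations are clustered into clones with a finite binomial-mixture EM on
the raw read counts (`cluster_ccf()`): cluster $k$ has a per-region
prevalence $\theta_{kr}$, and an alt count is
$\mathrm{Bin}(d_{ir},\, \theta_{kr} c_{ir})$ with $c_{ir}$ the CCF-to-VAF
factor above. This replaces the Dirichlet-process MCMC tools used for
the same inferential target in the literature with something
deterministic and self-contained. Restarts use a short-run screen
(25 EM iterations each) over structured initializations — k-means and
Ward-cut centroids of the naive CCF matrix, plus quantile splits of each
cluster of the previous $K$'s best fit — and the best short run is
polished to convergence.

The number of clusters is selected by **AIC**, not BIC, and this is a
considered choice: with $\sim$30 mutations per clone at depth 100, a
regionally fixed clone (prevalence 1.0 in one region) sitting next to a
sibling at prevalence $\sim$0.7 in the same region yields a
log-likelihood gain of only $\sim$6 nats when split — below BIC's
penalty ($\sim$19 nats at these sizes) but above AIC's (8). BIC therefore
merges exactly the clones whose separation matters most downstream
(clonal-illusion detection); AIC recovers them at the cost of occasional
over-splitting, which is harmless because clonality labels come from
presence patterns and the tree construction tolerates near-duplicate
clusters.

## Presence, clonality, illusions

A mutation is present in a region when VAF > 0.02 or more than three
reads support the alternate allele; clonal when present in every region,
subclonal otherwise; and a *clonal illusion* when it is subclonal yet its
CCF reaches 0.9 in at least one region where it is present — single-region
sampling would have called it clonal. The 0.9 cutoff is a parameter
(`illusion_ccf`), since no canonical value exists. Illusion flags are
evaluated on cluster-smoothed CCFs (each mutation inherits its cluster's
prevalence vector): single-mutation CCFs at depth 100 have a standard
error near 0.15, which would make the flag a coin toss near the
threshold, whereas cluster means are stable. Even so, a mutation whose
read counts genuinely sit between two clusters can be assigned to the
wrong one; this residual Bayes error (about 1% of illusion mutations at
the default simulation conditions) is irreducible at finite depth.

## Clone trees

`build_clone_tree()` attaches clusters under the truncal cluster subject
to the **cross rule** (a child's prevalence never exceeds its parent's in
any region) and the **pigeonhole constraint** (children's prevalences sum
to at most the parent's per region), both within a tolerance
`eps = 0.05` chosen to absorb CCF sampling noise. When several parents
are feasible, the cluster nests under the feasible parent with the
smallest mean prevalence (deepest nesting), which makes the construction
deterministic. An exhaustive validator (`validate_clone_tree()`) and a
full enumerator over parent vectors (`enumerate_feasible_trees()`)
provide independent oracles; trees are tested to be feasible, members of
the enumerated feasible set, and to carry the true linear-vs-branched
label.

# Copy-number instability

Segment calls work on ploidy-normalized log2 ratios
($\log_2((\rho\,cn_{seg} + (1-\rho)\,cn_n)/\mathrm{ploidy})$ with gain,
loss and amplification thresholds at $\log_2(2.5/2)$, $\log_2(1.5/2)$
and $\log_2(4/2)$. Arm events follow the 75/90 rules: clonal when every
region has $\ge$75% of the arm altered in the same direction and one
region reaches 90%; subclonal when any region exceeds 75%. wGII is the
mean over the 22 autosomes of the fraction of covered length whose total
copy number departs from the *rounded sample ploidy* — a ploidy-aware
baseline, so a uniformly doubled genome is not scored as globally
aberrant — and genome doubling is proxied by ploidy $\ge 3$. The
subclonal SCNA fraction partitions each chromosome at the union of all
regions' breakpoints and classifies each altered minimal interval as
clonal (same non-neutral direction everywhere) or subclonal.

Mirrored subclonal allelic imbalance (`detect_msai()`) works on phased
heterozygous SNP B-allele fractions (alt/(alt+ref), the bounded
convention) with coverage $\ge$ 10x: per arm and region, a one-sample
t-test of the haplotype-A fraction against 0.5 at $\alpha = 0.01$ gives
a signed direction, and an event requires two regions significant in
opposite directions with SNPs spanning $\ge$75% of the arm. The
simulator provides true phase; for real data SNPs would be co-segregated
by the sign of imbalance in the most imbalanced region first.

# Methylome heterogeneity

Bulk methylation is modeled as a purity- and copy-weighted mixture of
tumor and normal rates; `deconvolve_methylation()` inverts it,

$$m_t = \frac{m_b(\rho n_t + n_n(1-\rho)) - n_n m_n (1-\rho)}{\rho n_t},$$

clamping to $[0,1]$. CpGs are averaged into fixed-width bins (3 kb
genome-wide, 1 kb for differential analysis; $\ge$3 covered CpGs per
bin, unweighted means — coverage weighting is a documented alternative
the source material does not specify). DMR calling is a two-proportion
z-test on pooled counts with BH correction, hyper/hypo at q < 0.01 and
|difference| > 0.25; element enrichment uses two-sided Fisher tests.
APITH is the mean pairwise Euclidean distance between regions over the
DMR-bin profiles, $\frac{2}{k(k-1)}\sum_{i<j} d_{ij}$, unbiased in the
number of regions $k$.

Epiallele diversity at 4-CpG loci ($\ge$60 reads) uses the 16-pattern
frequencies $p$: Shannon entropy $-\sum p\log_2 p$ (bits, unnormalized —
external tools differ in normalization and none is canonical),
epipolymorphism $1-\sum p^2$, and PDR, the fraction of reads neither
fully methylated nor fully unmethylated. All three are verified against
a brute-force per-read enumeration to $10^{-12}$.

# RNA heterogeneity

Genes are kept at $\ge$1 TPM in $\ge$20% of samples and analyzed as
log2(TPM+1). The per-gene intra score is the mean over patients of the
within-patient standard deviation; the inter score is the standard
deviation of patient means; quadrants split both at their means
(I high-intra/low-inter, II low/low, III high/high, IV low-intra/
high-inter). These definitions are this artifact's normative choice —
the literature delegates them to an external method without printing
formulas. Clustering concordance is the mean silhouette width of the
patient partition on the single-gene vector; note its null is *negative*
(about $-0.4$ for 10 patients of 4 regions) because the nearest of many
other clusters is closer than the own-cluster average by chance, so only
rankings and between-class comparisons are interpretable. Patient
RNA-ITH is the median pairwise $1-\rho_{Spearman}$ between regions, with
a saturation curve over region subsets (enumerated when few, 100 seeded
draws otherwise). Dosage association takes, per gene and patient, the
mean expression in copy-altered minus copy-neutral regions, tested by
paired t per direction; promoter (and first-exon, gene-body) methylation
association declares an element differentially methylated between two
regions when any shared CpG passes Fisher p < 0.05 *and*
|level difference| $\ge$ 0.2.

# Immune infiltration and neoantigens

Population scores are mean log2(TPM+1) over marker genes; the registry
is configuration (a synthetic placeholder registry ships for simulated
runs — curated lists live in external publications). Regions are split
into two groups by Ward-D2 hierarchical clustering on the Manhattan
metric and the group with the higher total-TIL score is "high"; patients
mixing labels are heterogeneous. HLA-LOH timing is clonal / subclonal /
none by the per-region loss calls. The neoantigen cascade keeps
candidates with mutant percentile rank $\le$ 2 binding at least as well
as the wild-type peptide; clonally lost alleles exclude their epitopes,
subclonally lost alleles only when every clone carrying the epitope (the
mutation's clone plus descendants) lost the allele; expression requires
$\ge$5 reads at the site with $\ge$3 mutant.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| patients / regions | 6 / 3–5 | desk-scale mirror of a 36-patient, 3–6-region design |
| depth | 100x | exome-like depth where presence/CCF rules are meaningful |
| purity | 0.6–0.9 | pathology-screened cohorts require $\ge$60% |
| clones | 2–5 | observed cluster counts per patient span a few to ~13 |
| mutations/clone | ~30 (Poisson) | enough for signature refits and stable cluster means |
| GD fraction | 0.7 | genome doubling is reported in ~70% of patients |
| MSAI fraction | 1/3 | mirrored events are reported in about a third of patients |
| DMR fraction / shift | 0.1 / 0.4 | planted shifts comfortably above the 0.25 call threshold |
| epiallele disorder | 0.02–0.25 (+0.2 on altered segments) | sweeps entropy from near 0; the boost encodes the CIN–epiallele coupling |
| dosage effect | 0.5 log2/copy | typical bulk dosage response |
| infiltration states | log2 TPM 2 vs 6; 21/45/33% high/low/het patients | two separable marker states at reported patient proportions |

Clone prevalences are allocated top-down: in each region a parent either
hands its full prevalence to one child (regional fixation — the source
of clonal illusions) or splits a sub-unity share by a scaled Dirichlet
draw; allocations are floored at 0.15 (below which a clone is absent)
and capped at 0.8 unless fixed, so true prevalences lie in
$\{0\}\cup[0.15,0.8]\cup\{1\}$ and the 0.9 illusion threshold is never
straddled by construction. Sibling clones are re-drawn until their
prevalence vectors *cross* (neither dominates the other in every
region): crossing siblings cannot be arranged in a chain under the cross
rule, which makes the branched/linear label identifiable from
prevalences alone; a parent present in fewer than two regions cannot
host crossing siblings, so its surplus children re-attach to the root.
Read counts are binomial at Poisson($\bar d$) depths; the matched normal
carries no variant reads (sequencing-error profiles are out of scope).
Epiallele reads start from a dominant pattern and flip each CpG
independently with probability disorder/2, so one parameter sweeps all
three diversity metrics from degenerate to maximal.

What the generator deliberately does **not** emulate: alignment and
calling artifacts, sequencing error, real mutation hotspots or real
marker genes, focal (sub-arm) copy-number structure, subclonal genome
doubling, and cell-type deconvolution complexity beyond a two-state
infiltrate. Passing tests therefore demonstrate correctness of the
*rules and estimators* under the stated statistical model, not
robustness to real-data artifacts.

# Numerical choices and test scale

Feasibility tolerance on prevalence comparisons is 0.05 in the pipeline
(sampling noise) and $10^{-9}$ when validating exact truth prevalences.
Binomial success probabilities inside the EM are clamped to
$[10^{-6}, 1-10^{-6}]$; deconvolved methylation and CCFs are clamped to
$[0,1]$; homozygous-deletion log ratios floor at $-10$. Ties in variable-
bin ranking break on bin id; the TIL "high" group is decided by the
total-TIL column when present, otherwise the overall mean score.

The test suite runs the pipeline at deliberately desk-scale sizes — ten
10-patient cohorts for clonality recovery, 200 planted and 1000 null
arms for mirrored-imbalance power and specificity, ten 550-bin
methylomes for DMR recovery, 150 simulated patients for the APITH bias
regression, 500 null replicates for dosage type-I error, and one
6-patient cohort run twice for byte-identical end-to-end determinism —
sizes at which every recovery property stabilizes while the whole suite
stays inside a coffee break.

# Known limitations

* Clonal-illusion flags inherit cluster assignments; mutations whose
  read counts sit between two clusters can be mis-flagged at a rate set
  by the likelihood overlap (~1% of illusion mutations at default
  conditions). Deeper sequencing, not a better estimator, is the remedy.
* The concordance statistic's negative null bias (above) means absolute
  values are not comparable across cohort layouts with different region
  counts per patient.
* Arm-grained copy number in the simulator means dosage and
  epiallele–SCNA couplings are tested at arm resolution; the estimators
  themselves accept arbitrary segments.
* The MSAI caller assumes phased input; tumor-informed phasing for real
  data is not implemented here.
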