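# leatsubtype

Transcriptional subtyping of long-term epilepsy-associated tumors (LEATs).

LEATs — gangliogliomas (GG), dysembryoplastic neuroepithelial tumors (DNT)
and pleomorphic xanthoastrocytomas (PXA) — are mostly benign causes of
drug-resistant epilepsy, but a subset recurs and progresses, and histology
alone separates the two courses poorly. This package implements, as a tested
and reproducible pipeline, the expression-based subtyping workflow used to
stratify such cohorts:

1. **Cohort assembly** — merge log-expression matrices from several datasets
   over their shared gene space and remove dataset (batch) effects with the
   parametric empirical-Bayes location/scale model (ComBat):
   standardised values are adjusted as
   `(z_gj - gamma*_bg) / delta*_bg`, where the per-(batch, gene) location
   `gamma*` and scale `delta*²` estimates are shrunk toward a normal /
   inverse-gamma prior fitted across genes by the method of moments.
2. **Subgroup discovery** — partitioning around medoids (PAM, BUILD + SWAP)
   on the 1000 most variable genes under a `1 - Pearson` sample distance;
   the cluster number k is chosen over k = 2..10 by the mean silhouette
   width `s(i) = (b(i) - a(i)) / max(a(i), b(i))`; samples with `s(i) < 0`
   are removed as non-core; stability is corroborated by subsampled
   consensus clustering (co-clustering CDF and its area per k).
3. **Signature genes** — nearest shrunken centroid (NSC) classification:
   `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` soft-thresholded by a
   cross-validated shrinkage `delta`, with per-gene average ranks across CV
   folds, one-vs-rest Welch t-tests with Benjamini-Hochberg FDR, and
   per-sample subgroup affiliation scores (softmax of the NSC discriminant).
4. **Enrichment** — permutation-based pre-ranked GSEA driven by the
   per-subgroup shrunken classifier scores (weighted Kolmogorov-Smirnov
   running sum, gene-label permutation null, sign-stratified FDR) and GSVA
   (kernel-CDF ranks, per-sample random walk) for set-by-sample scores.
5. **Clinical statistics** — cluster-marker association by one-vs-rest
   Fisher exact tests, rank-sum / one-way ANOVA group comparisons with BH
   adjustment, Kaplan-Meier curves, log-rank tests and Cox hazard ratios for
   progression-free survival stratified by BRAF V600E status.

Because the original patient-level expression data are not distributable, the
package ships a first-class synthetic cohort generator
(`simulate_cohort()`) that plants four transcriptional subgroups
(11/18/13/11 samples across three batches, 100 marker genes each at +1.5 SD)
with outcome-coupled covariates: a recurrence-prone, BRAF-enriched subgroup
(42% recurrence, 71% BRAF alteration) and a 4-fold progression hazard for
BRAF-mutant samples. A packaged 18-patient clinical table
(`load_table1()`) carries the real cohort's printed characteristics.

## Worked example

```r
library(leatsubtype)

report <- run_pipeline(pipeline_config(
  simulation = cohort_config(seed = 7),
  consensus_reps = 30, gsea_n_perm = 500, seed = 7))
report
#> <pipeline_report> k = 4 (52 core of 53 samples), cluster sizes: C1=11, C2=18, C3=13, C4=10
#>   NSC cross-validated accuracy: 1.000 (delta = 0.11)

round(report$selection$mean_silhouette, 3)
#>     2     3     4     5     6     7     8     9    10
#> 0.039 0.057 0.085 0.054 0.034 0.014 0.018 0.010 0.011

report$clinical$braf$per_cluster
#>   cluster  n n_marker odds_ratio            p            q
#> 1      C1 11        0          0 2.207542e-02 2.943389e-02
#> 2      C2 18       15        Inf 1.820867e-10 7.283468e-10
#> 3      C3 13        0          0 1.058604e-02 2.117208e-02
#> 4      C4 10        0          0 4.635639e-02 4.635639e-02
```

Reading this output: the silhouette scan peaks at k = 4, one borderline
sample is dropped as non-core, the nearest-shrunken-centroid classifier
separates the four subgroups perfectly in cross-validation, and BRAF
alterations concentrate in cluster C2 (15/18 carriers, Fisher q ≈ 7e-10) —
the recurrence-prone subgroup the simulation plants. `report$enrichment$gsea`
holds the per-subgroup pre-ranked GSEA tables (the four planted marker sets
reach FDR q < 0.05 in their own subgroup), and `report$clinical$survival`
the Kaplan-Meier / Cox summary of BRAF-stratified progression-free survival.

A shell entry point with the same stages is provided:

```sh
Rscript scripts/run_pipeline.R --seed 1 --outdir out/          # simulated
Rscript scripts/run_pipeline.R --expr expr.tsv --clinical clinical.tsv \
    --gmt sets.gmt --outdir out/                               # own data
```

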