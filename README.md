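# lncMethNet

Tools for studying DNA-methylation-mediated regulation of long non-coding
RNAs (lncRNAs) in tumor/normal cohorts, as an end-to-end, fully testable
pipeline on Infinium 450K-style methylation, RNA-seq-style expression,
miRNA interaction tables and clinical follow-up.

## Who this is for

Computational epigenomics groups who want the classic "promoter
methylation → expression → ceRNA network → prognosis" integration
workflow as reusable, seeded, unit-tested R functions rather than a
one-off script stack. Every stage runs on plain local files; a built-in
synthetic multi-omics generator with planted ground truth makes the whole
workflow verifiable without any downloads.

## The analysis

1. **Promoter methylation.** Per-probe beta values
   (β = Methy/(Methy+Unmethy) ∈ [0,1]) are filtered (probes missing in
   > 30% of samples dropped, the rest mean-imputed) and averaged over the
   strand-aware 2 kb window upstream of each lncRNA TSS. Tumor and normal
   promoter-level distributions are compared with a two-sample
   Kolmogorov–Smirnov test.
2. **Differential calling (SAM).** A permutation-based SAM statistic
   d = (x̄_T − x̄_N)/(s + s₀) with empirical q-values:
   FDR(t) is the expected number of permuted |d*| ≥ t over the observed
   count, and q is its running minimum over thresholds. Calls:
   DML (q ≤ 0.05 and |Δβ| ≥ 0.1), DEL (q ≤ 0.05),
   DEG (q ≤ 0.05 and FC ≥ 2 or ≤ 0.5).
3. **Classification.** DML ∩ DEL lncRNAs split into HMLncs/LMLncs by
   methylation direction and into four groups by expression direction:
   high-up, high-down, low-up, low-down.
4. **ceRNA network.** For every candidate lncRNA–mRNA pair: Pearson
   correlation across tumor samples (PCC > 0, p ≤ 0.01) and a
   shared-miRNA hypergeometric test
   P = 1 − Σ_{i<m} C(M,i)C(N−M,n−i)/C(N,n) (≥ 2 shared miRNAs,
   P ≤ 0.01). The four groups seed four sub-networks; mRNAs with degree
   ≥ 5 are hubs.
5. **Enrichment.** Nearest-gene cis assignment (a transparent stand-in
   for region-based web tools), hypergeometric gene-set enrichment with
   Benjamini–Hochberg FDR, a GO `is_a` term network with connected
   components, and miRNA–disease hypergeometric enrichment.
6. **Survival.** Multivariate Cox fit on hub-module expression
   (Breslow ties, z-scored covariates), prognostic index
   PI = β₁x₁ + … + β_p x_p, median split into high/low risk,
   Kaplan–Meier curves and the log-rank test. Coefficients can be
   transferred to an independent cohort without refitting.

## Worked example

```r
library(lncMethNet)

run <- run_synthetic_demo("demo", simulation_config(seed = 42))
print(run)
```

prints (abridged):

```
inputs: 200 lncRNAs, 300 genes, 2000 probes, 40 tumor / 20 normal samples
promoter levels for 183 lncRNAs (17 without probes dropped); K-S tumor vs normal D = 0.2240, p = 0.000205
differential: 80 DMLs, 80 DELs, 47 DEGs; 80 classified lncRNAs (40 HMLncs, 40 LMLncs)
groups: high-up 20, high-down 20, low-up 20, low-down 20
background ceRNA network: 66 lncRNAs, 37 mRNAs, 184 edges
sub-network high-down: lncRNAs 20, miRNAs 47, mRNAs 6, edges 111, mean_lnc_degree 5.55, n_hub_mRNAs 6
survival high-up: no hub mRNAs, module not assessable
survival high-down: 6 hub mRNAs, log-rank chisq = 6.046, p = 0.01394
survival low-down: 4 hub mRNAs, log-rank chisq = 0.2938, p = 0.5878
```

The generator planted 20 lncRNAs per group (promoter shift ±0.25 beta
units coupled to a ∓/±1.5 log2 expression shift): the pipeline recovers
all 80 into their true groups, the K-S test picks up the global
methylation difference, and only the high-down group — whose planted
mRNA module carries nonzero hazard coefficients — separates patients
into risk groups significantly. Inputs land in `demo/input/`, stage
outputs (TSV/BED/edge lists, `run.log`, md5 `manifest.tsv`) in
`demo/output/`.

Real data runs use the same entry point with your own files:

```r
run <- run_pipeline(list(
  lnc_gtf = "lncrna.gtf", gene_gtf = "genes.gtf", manifest = "probes.tsv",
  beta = "beta.tsv", lnc_expr = "lnc_expr.tsv", mrna_expr = "mrna_expr.tsv",
  mir_lnc = "mir_lnc.tsv", mir_mrna = "mir_mrna.tsv",
  clinical = "clinical.tsv", samples = "samples.tsv",
  term2gene = "term2gene.tsv", isa_edges = "isa_edges.tsv",
  disease2mirna = "disease2mirna.tsv", outdir = "results"))
summary(run)
```

## Vignette

`vignettes/methylation-regulated-lncRNAs.Rmd` documents the models, the
synthetic-data design, numerical choices and known limitations.
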