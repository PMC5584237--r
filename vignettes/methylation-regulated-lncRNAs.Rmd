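---
title: "Methylation-regulated lncRNAs: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-regulated lncRNAs: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

lncMethNet implements the integrative workflow that asks whether promoter
DNA methylation drives lncRNA dysregulation in a tumor/normal cohort, and
whether the mRNA modules those lncRNAs engage through shared-miRNA
(ceRNA) competition carry prognostic information. This vignette is the
package's own account of the models, the knobs that matter, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where conventions diverge.

# Models and assumptions

## Promoter methylation

A probe's methylation is the intensity ratio β = Methy/(Methy+Unmethy),
undefined (missing) when both intensities are zero. Probes missing in
strictly more than `max_missing_frac` (default 0.30) of samples are
removed; remaining gaps get the probe's cross-sample mean. The filter is
strict ("more than 30%"), so a probe missing in exactly 30% of samples
survives. Promoters are the `promoter_window` (default 2000 bp) region
immediately upstream of the TSS, strand-aware, in 0-based half-open
coordinates: `[TSS-w, TSS)` on `+`, `[TSS, TSS+w)` on `-`, clipped at
coordinate 0. A probe sitting exactly at a `+`-strand TSS is therefore
*outside* the promoter; the boundary is arbitrary and we chose
consistency with the half-open convention used everywhere else. A probe
may serve several overlapping promoters. The lncRNA's methylation level
is the unweighted mean β of its promoter probes; lncRNAs without probes
are excluded from methylation stages only.

The tumor-vs-normal comparison of promoter methylation uses the
two-sample Kolmogorov–Smirnov statistic on *per-lncRNA group means* (one
value per lncRNA per group), not on pooled per-sample values: the global
question is about the distribution across lncRNAs, and pooling samples
would entangle the two cohort sizes.

Annotation input is gene-level. If your GTF carries transcripts, collapse
them first; the conventional rule is the 5'-most transcript start on the
gene's strand, and `read_annotation()` keeps whatever gene-level records
you supply, so any collapsing rule can be applied upstream.

## SAM differential calling

For each feature, d = (x̄_T − x̄_N)/(s + s₀), with s the pooled standard
error and s₀ an exchangeability constant damping features with tiny
scatter. We set s₀ to the median of the per-feature s values — the
common deterministic simplification of the original coefficient-of-
variation search — with a percentile override (`estimate_s0`). s₀ is held
at its observed value across permutations.

q-values come from label permutations that preserve group sizes. At every
observed threshold t, FDR(t) is the expected number of permuted |d*| at
or above t (mean over permutations) divided by the observed count, and a
feature's q is the running minimum of FDR over thresholds up to its own
|d|, which enforces monotonicity of q in |d|. The mean (not the median)
of the permutation counts is used so that in the degenerate single-
feature case with full enumeration the q-value is exactly the permutation
tail fraction; `center = "median"` is available. `B = "exact"`
enumerates all tumor-label assignments and is refused above 20,000
assignments. Permutation counts use a relative 1e-8 tolerance when
matched against thresholds so that exact ties (e.g. the identity
assignment under enumeration) are never lost to last-bit arithmetic
differences between code paths.

Calls use the conventional inclusive thresholds: DML at q ≤ 0.05 and
|Δβ| ≥ 0.1 with the sign of Δβ = β̄_T − β̄_N defining
hyper-/hypomethylation; DEG at q ≤ 0.05 and fold change ≥ 2 or ≤ 0.5;
DEL at q ≤ 0.05 only, directed by the sign of the mean difference. For
expression matrices the pipeline computes the SAM statistic on
log2(x + 1) — SAM's pooled s₀ is scale-sensitive and raw RNA-seq-like
abundances would shrink d for low-expressed features — while fold
changes are taken from linear-scale group means with a pseudocount
ε = 0.01 guarding empty denominators. The classified set is the
intersection of DML and DEL calls, crossed into the four groups
(high-up, high-down, low-up, low-down).

## ceRNA network

Candidate edges are (DEL lncRNA, DEG mRNA) pairs sharing at least one
miRNA. An edge requires all four of: Pearson correlation > 0;
correlation p ≤ `pcc_p` (default 0.01; two-sided t on n − 2 df);
shared-miRNA count ≥ `min_shared` (default 2, reading "more than one
common miRNA" literally; set 1 to relax); and the upper-tail
hypergeometric p ≤ `hyper_p` (default 0.01) for the overlap m of the
lncRNA's M and mRNA's n interacting miRNAs within a universe of N
miRNAs. N defaults to the distinct miRNAs in the union of the two
loaded interaction tables — the natural closed universe of the data at
hand. Correlation is computed across tumor samples only (the network
describes the tumor state; `sample_scope = "all"` switches) and on
log2(x + 1) values (`log2_expr = FALSE` reverts), since correlation of
skewed linear-scale abundances systematically attenuates. Interaction
tables are deduplicated before any set operation.

Each classified group seeds a sub-network (its incident background
edges); mRNAs of degree ≥ `hub_threshold` (default 5) are hubs and the
mean lncRNA degree is edges per lncRNA node.

## Enrichment

The cis stage is a deliberate, transparent stand-in for region-based web
enrichment tools: each lncRNA maps to the protein-coding gene with the
nearest TSS within `max_distance` (default 1 Mb; ties resolve toward the
smaller coordinate, deterministically), and the resulting gene sets are
tested per term with the hypergeometric upper tail against the gene
universe of the loaded annotation, Benjamini–Hochberg adjusted,
significant at FDR ≤ 0.05. The region-length binomial model of those web
tools is *not* reimplemented. The term network restricts a child→parent
`is_a` table to the significant terms and reports weakly connected
components. miRNA–disease enrichment uses the same hypergeometric with N
the total distinct miRNAs of the annotation table and raw p < 0.05
(no multiple-testing adjustment — the convention for this screen), and
annotations are not propagated up the ontology.

## Survival

The hub-module analysis fits a multivariate Cox proportional-hazards
model (Breslow tie handling; convergence at relative log-likelihood
change < 1e-9 or 100 iterations) on z-scored module-gene expression.
Standardization is for numerical comparability across genes; the
prognostic index PI = Σ β_g x_g is computed on the same standardized
values, and the median split sends samples strictly above the median to
high risk, everything else (including exact ties) to low —
deterministic, at the cost of a one-sample imbalance under ties. An
all-tied PI vector is a degenerate split and an error. Kaplan–Meier
curves and the two-group log-rank test summarize the separation. A
sub-network without hub mRNAs is not assessable and says so
(`"no hub mRNAs"`); the pipeline records the note and continues.
`module_survival(..., transfer = )` applies a fitted model's
coefficients and standardization to an independent cohort, splitting at
that cohort's own PI median — both refit and transfer modes exist
because external validation practice varies.

# The synthetic-data generator

`simulate_study()` emulates the full input suite — annotation GTFs, a
probe manifest, a beta matrix, two expression matrices, two interaction
tables, clinical follow-up, term/disease/`is_a` annotation tables — with
planted, recoverable truth. Defaults are the reference study conditions
used by the test suite: 40 tumor / 20 normal samples, 200 lncRNAs,
300 genes, 150 miRNAs, 2000 probes, 20 planted lncRNAs per group,
Δβ = 0.25, log2 expression effect 1.5, 3 shared miRNAs per true ceRNA
pair, latent-factor co-expression 0.6.

Design, with rationale:

* **Geometry.** One synthetic chromosome; features on a 20 kb grid with
  ≤ 2 kb TSS jitter, so nearest-gene assignments never tie and probe
  placement is unambiguous. 90% of lncRNA promoters receive dedicated
  probes (~7 at defaults); the rest of the probes scatter uniformly, so
  some fall outside all promoters.
* **Methylation.** Per-probe baseline means are uniform on [0.3, 0.7]
  and samples draw from a Beta distribution with precision 60
  (sd ≈ 0.06), respecting the [0, 1] support like real beta values. The
  [0.3, 0.7] baseline keeps a ±0.25 planted shift inside the support
  without clamping, so the realized mean shift equals the nominal one.
  Tumor means of planted promoters shift by ±Δβ (clamped to
  [0.02, 0.98] with a warning if a custom configuration forces it).
  2% of entries go missing completely at random — enough to exercise
  the filter and imputation deterministically in expectation.
* **Expression.** Log-normal: log2 values are a uniform [3, 8] baseline
  plus N(0, 0.7²) noise. Planted lncRNAs shift ±1.5 log2 units in
  tumor; partner mRNAs shift the same signed amount. True ceRNA pairs
  share a tumor-sample latent factor with weight
  w = σ√(ρ/(1−ρ)) so the expected pair correlation is ρ
  (`cerna_cor`); the factor's lognormal variance contribution is
  subtracted from the mean (w²·ln2/2 in log2 units) so expected
  linear-scale fold changes stay exactly 2^±1.5.
* **Network truth.** The high-down and low-down groups each share one
  module of 6 partner mRNAs (every group lncRNA pairs with every module
  gene, all loading on one group factor and one shared miRNA set), so
  those sub-networks develop hub mRNAs. High-up and low-up lncRNAs get
  one private partner and private miRNA set each, so their sub-networks
  stay hub-less. Each feature also gets 3 background miRNA interactions
  from the 150-miRNA universe; at these rates a random pair shares ≥ 2
  miRNAs with probability ≈ 8e-4, so planted overlaps dominate.
* **Survival.** Tumor survival is exponential with log-hazard
  Σ β_g z_g over the high-down module genes (z: expression standardized
  across tumor samples), β_g = 0.3 each — a hazard ratio of about 1.35
  per SD per gene, a realistic moderate module effect — on a baseline
  hazard of 0.002/day (median ≈ 1 year at null covariates). The
  low-down module's coefficients are zero, so only the high-down module
  is truly prognostic. Censoring is independent and uniform: the
  per-sample upper bound is x/λ_i with x solving (1−e^−x)/x =
  `censor_rate`, which makes each sample's censoring probability exactly
  the configured rate.
* **Determinism.** Every modality draws from its own stream derived
  from the master seed, and the planted set is chosen from the
  *designed* probe-covered promoters, so changing `n_probe` leaves the
  expression draws untouched. Fixed seed ⇒ byte-identical files.

What the generator does **not** emulate: 450K probe chemistry (type
I/II bias), copy-number or batch confounding, read-count sampling noise,
ontology structure beyond a random `is_a` forest, and correlated
censoring. Passing tests therefore demonstrate correctness of the
statistical machinery and recoverability under idealized noise — not
robustness to array artifacts or confounding in real cohorts.

# Problem sizes and test design

The suite verifies exactness against independent oracles (exhaustive
hypergeometric enumeration for all N ≤ 12, covariance-form Pearson on
1000 random vectors at 1e-12, longhand Kaplan–Meier/log-rank tables,
full SAM permutation enumeration at n = 3+3, a grid-search argmax of the
Breslow partial likelihood, union-find components, brute-force interval
and incidence scans), error-rate control under global nulls (20
all-null SAM replicates of 200 features at 5+5; 500 null log-rank
replicates at n = 200), and planted-truth recovery (10-seed suite at
the default study conditions; ceRNA recovery at 60 tumor samples; Cox
recovery at n = 500 over 20 seeds; module separation at n = 300).
These sizes keep the default test run within a few minutes while
leaving Monte-Carlo margins far from the asserted bounds.
`scripts/acceptance.R` recomputes the same quantities from scratch under
a caller-supplied seed.

# Known limitations

* SAM permutation FDR is conservative when many strong true effects
  inflate the permuted null (effects are not removed before permuting);
  at the planted effect sizes this costs nothing, but weak-effect
  regimes will lose power.
* The ceRNA stage conditions on nothing: no partial correlation against
  miRNA expression, no direction of regulation.
* The cis stand-in assigns one nearest gene per lncRNA; region-based
  tools integrate over regulatory domains and will differ on real data.
* Proportional hazards is assumed, not checked; no clinical covariate
  adjustment, no time-dependent effects.
* The GO term network uses the annotation as given — no true-path
  closure — so component counts depend on the annotation's propagation
  state.
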