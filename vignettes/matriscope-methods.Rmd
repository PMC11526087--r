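---
title: "Methods: matrisome-centric profiling of multi-plex TMT proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrisome-centric profiling of multi-plex TMT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriscope)
```

# Overview

matriscope implements an extracellular-matrix (ECM) centric analysis of
quantitative proteomics from decellularized tissue. The setting it models
is a multi-plex TMT experiment on patient-derived decellularized ECM
(pdECM): tissue samples from tumor (TUM), normal adjacent to tumor (NAT),
lymph-node metastasis (LNM) and normal tissue from non-cancer patients
(NN) are labeled across several TMT 11-plexes, each plex carrying nine
tissue samples plus two aliquots of a pooled common control in the 131N
and 131C channels. Downstream, the package annotates proteins against the
matrisome (collagens COL, ECM glycoproteins GLY, proteoglycans PRO, ECM
regulators REG, ECM-affiliated proteins AFF, secreted factors SEC), calls
differential matrisome proteins between tissue groups, defines a
histology-enriched protein program, locates the cellular origin of that
program in single-cell expression data, and asks whether a bulk cohort's
expression of the program stratifies survival.

Every stage runs on synthetic data generated by the package itself, so
the entire analysis is testable without any external download. The
generator is first-class, tested code: its planted ground truth is what
the recovery tests measure against.

# Two-stage TMT normalization

Reporter-ion intensities differ between channels (loading, labeling
efficiency) and between plexes (instrument drift between runs). The
normalization runs in two stages, both keeping matrices on the linear
intensity scale between steps and moving to log2 only inside each
computation.

**Stage 1 — within-channel median centering.** For channel $j$ with
median $m_j$ of its log2 intensities, every entry becomes
$2^{\log_2 x_{ij} - m_j + \bar m}$ where $\bar m$ is the mean of all
channel medians. Afterwards every channel has the same log2 median
(checked in tests to 1e-9). Adding back the mean of the medians keeps the
output on the familiar intensity scale instead of centering at zero.
Missing entries propagate; medians use observed entries only. The
centering direction (value minus median) is the only direction consistent
with a common median; it is isolated in one function, `median_center()`.

**Stage 2 — cross-plex reference scaling.** Each plex's second reference
channel (R2, 131C) carries the same pooled control, so it can bridge
plexes. For protein $i$ in plex $p$:
$y_{ij} = x_{ij} / x_{i,R2_p} \cdot a_i$, with $a_i$ the arithmetic mean
of the protein's R2 intensities across plexes. We read "the average
normalized intensity of the R2 column" per protein across plexes (the
reading that makes R2 a cross-plex bridge; afterwards every R2 channel of
a protein equals $a_i$ exactly). The alternative reading — one grand mean
over all proteins — is exposed as `r2_mean = "grand"`. Within-plex ratios
are untouched by stage 2, and on zero-noise synthetic data with planted
plex batch factors the batch term cancels exactly (tested to 1e-9).
Proteins lacking a positive R2 intensity in any plex cannot be bridged;
they are excluded and counted in the QC report. The first reference
channel (R1, 131N) is used only for QC: the per-plex median log2 ratio of
R1 to R2 should sit near zero since both carry the same pooled control.

The stage-1 description speaks of peptide abundance, but this package
ingests and normalizes the protein-level matrix — the only matrix the
pipeline sees.

# Matrisome profiling

Proteins are annotated by exact gene-symbol match (case-sensitive by
contract; unmatched proteins are "none"). The relative percent
composition (RPC) of protein $i$ in sample $s$ is
$100 \, x_{is} / \sum_k x_{ks}$, using all detected proteins as the
denominator so that per-category sums read directly as shares of total
intensity; a matrisome-only denominator is a documented option of the
surrounding analyses. Category composition sums member-protein RPC per
sample and compares groups with Welch's t-test per category. The
cumulative-coverage count is the smallest number of top-ranked proteins
whose mean RPC reaches a threshold (default 90%) of the total —
monotone in the threshold by construction.

Sample clustering z-scores each protein across samples (standard heatmap
practice), then applies Euclidean distance and agglomerative clustering;
the linkage is selectable (`average` default, the common heatmap choice,
plus single/complete/ward). PCA runs on log2 intensities of matrisome
rows (log2 stabilizes variance across the wide MS dynamic range; a
linear-scale option remains). Component signs are fixed by making the
largest-magnitude loading positive so embeddings reproduce across
platforms.

# Differential matrisome proteins and the PEM set

`welch_dep()` compares two sample groups per protein. Two deliberately
different scales are used, as in standard practice for this analysis:

* the **fold change** is the ratio of linear-scale group means;
* the **test** is Welch's two-sided t-test on log2 intensities with
  Welch–Satterthwaite degrees of freedom.

A protein is a DEP when $|\log_2 FC| > 0.5$ (i.e. $FC > \sqrt 2$) and
$p < 0.05$. No multiple-testing correction is applied by default — DEP
calling uses raw p-values, stated prominently here and in the function
documentation; a Benjamini–Hochberg mode is available but off by
default. Zero intensities are treated as unquantified and excluded from
the log2 test; proteins with fewer than two observations in a group are
excluded and counted.

The PEM set (PCC-NOS-enriched matrisome proteins) is defined from the
contrast of PCC-NOS tumors against non-PCC-NOS tumors: only DEPs on the
PCC-NOS-enriched side qualify. Paired analysis computes per-patient
$\log_2(\text{TUM}/\text{NAT})$ for patients with both samples, the
per-protein median, and flags patients running against the median's
direction.

# Single-cell integration

Cell-type-specific genes are found one-vs-rest with a Wilcoxon rank-sum
test per gene (normal approximation with tie and continuity correction,
hand-vectorized so that `stats::wilcox.test` remains an independent
oracle in the tests), BH-adjusted within each cell type; specificity
requires adjusted $p < 0.01$ and a positive effect. A gene's cellular
origin is the cell type with the highest average normalized expression,
granted only if the gene is specific somewhere; otherwise it is
unassigned. The normalized layer is counts scaled to 10,000 per cell then
log1p; the TPM layer (scaled to 1e6, no length term for droplet counts)
is used only for score correlations.

Fibroblasts are subclustered on matrisome genes: z-scored normalized
expression, PCA to 20 components, a k-nearest-neighbor graph (k = 20,
Euclidean in component space) and Leiden modularity optimization at
resolution 0.5 — all parameters exposed, all defaults the analysis
constants above, clustering seeded and deterministic. With the modularity
objective the resolution-to-zero limit merges a *connected* graph into
one community; strongly separated populations yield a disconnected graph
whose components are never merged, which is the behavior the tests pin
down.

# Single-sample gene-set scoring

One audited scorer serves both per-cell and per-bulk-sample scoring
(`sc_score()` / `ssgsea_bulk()`). Genes are ranked by expression with
average ranks on ties. Walking the ranked list from the highest-expressed
gene down, the in-set cumulative distribution accumulates
$\mathrm{rank}^{\alpha}$ weights normalized over the set
($\alpha = 0.25$), the out-of-set distribution accumulates uniform
weight, and the enrichment score is the sum of their differences over
all positions. The tests enumerate this running sum by brute force over
every ordering of 5–7-gene toys and require exact agreement. Because the
statistic is rank-based, any strictly monotone per-sample transformation
of expression leaves scores unchanged — also tested. A Gaussian-kernel
GSVA variant is out of scope; the rank statistic is the package's single
scoring primitive.

# Bulk scoring and survival

The top-30 marker selection sorts a ranked marker table by log2 fold
change (ties alphabetical). Score vectors are compared by Pearson
correlation with the p-value from the t-distribution on $n-2$ degrees of
freedom. Patients are dichotomized at the mean score by default (median
optional); a value exactly at the cutpoint goes to the high group — a
documented convention. Survival uses the Kaplan–Meier product-limit
estimator and the log-rank test (k-group chi-squared with $k-1$ df),
computed via the survival package behind the package's own interface;
tied event times follow the standard simultaneous risk-set convention.

# The synthetic-data generator

The generator emulates the study design the analysis assumes, and its
defaults are those conditions:

* five TMT 11-plexes, nine tissue samples plus two reference channels
  each; group sizes 19 TUM / 17 NAT / 5 LNM / 4 NN over 23 patients;
  PCC-NOS assigned to 4 tumor patients by default, the remaining tumors
  lumped as non-PCC-NOS;
* 4838 proteins of which 376 matrisome, split over categories in
  proportion to the detected counts 37 COL / 102 GLY / 18 PRO / 99 REG /
  55 AFF / 63 SEC (these proportions are normalized by their sum when
  sizing the catalog);
* intensities are log-normal: log2 intensity = per-protein baseline
  (N(18, 3.5)) + per-plex batch (N(0, 0.5)) + planted effect + residual
  noise (N(0, 0.3)). MS data are conventionally modeled as log-normal;
  no generative model is stated by the analyses this emulates, so these
  are the package's own choices. The baseline sd of 3.5 log2 units
  reproduces the 4–5 orders of magnitude of dynamic range typical of
  reporter-ion data, which is what places the 90%-coverage counts in the
  hundreds rather than the thousands;
* reference channels carry, pre-noise, the pooled arithmetic mean of all
  sample channels of their protein (a pooled common control), times
  their plex's batch factor, with independent noise draws per reference
  channel — the two references in a plex are exchangeable replicates;
* planted tumor effects are added (log2 scale) to TUM channels only, and
  planted PCC-NOS effects to TUM channels of PCC-NOS patients only;
* matrices are complete by default; a missing-at-random rate is an
  optional knob, since no missing-value pattern is prescribed for the
  design being emulated.

The single-cell generator draws negative-binomial counts (size 2) around
log-normal per-gene baselines, elevates planted origin genes by 8-fold
(log2 effect 3) in their assigned type, and over-expresses a planted
program 4-fold in a designated fibroblast subpopulation (30% of
fibroblasts by default). The bulk generator gives every patient a latent
standardized program score $z$, shifts program-gene log2 expression by
$z$, scales columns to TPM (sum 1e6), and draws exponential survival
times with log-hazard increasing by the configured amount per unit of
$z$, under uniform administrative censoring (12–60 months; baseline
median survival 24 months at $z = 0$).

What the generator does *not* emulate: peptide-level spectra, missed
cleavages, TMT isotope-impurity cross-talk, ambient RNA or doublets,
compositional dependence between proteins, or non-proportional hazards.
Passing recovery tests therefore demonstrates that the implementations
compute what they claim on data satisfying their assumptions — not that
those assumptions hold in any particular real dataset.

# Problem sizes used in the tests

The default design (4838 proteins, 55 channels) generates in well under
a second, so design-level checks run at full scale. Recovery and
null-calibration tests use scaled-down catalogs (60–1000 proteins,
25–100 cells per type, 80–400 patients) chosen to keep each property
estimable with comfortable margins: e.g. differential recovery uses 50
replicates of 100 proteins at 10 vs 10 samples, planted log2 effect 1
and noise sd 0.3 (per-protein power near 1, so a 0.95 sensitivity bound
has headroom), and the log-rank power check uses 200 replicates at n =
400 with a planted log-hazard slope of 1.

# Numerical choices and degenerate inputs

* Medians and means over observed entries; missingness propagates.
* Non-positive intensities abort normalization unless masked as NA;
  channels that are entirely missing abort with the channel named.
* Constant protein rows are dropped (with a message) before z-scoring
  for clustering; zero-variance genes are excluded from score
  correlations and reported.
* Ties: average ranks in all rank statistics; alphabetical tie-breaks in
  all top-n selections; value-at-cutpoint goes high in dichotomization.
* Degenerate splits (all scores equal), empty gene sets, gene sets
  covering every gene, and single-group survival tables are errors; an
  empty PEM set is a warning, not an error, since a null contrast is a
  legitimate outcome.

# Known limitations

The package normalizes protein-level matrices only (no PSM/peptide
roll-up or isotope-purity correction), performs no imputation, no
moderated (limma-style) statistics, no Cox regression or multivariable
adjustment, and no optimal-cutpoint scanning. GO-term enrichment of
abundant proteins is out of scope (it requires an external annotation
service). UMAP layouts and heatmap rendering beyond the provided plot
helpers are likewise out of scope.
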