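# matriscope

Matrisome-centric analysis of multi-plex TMT proteomics from
decellularized tissue, with single-cell and survival integration.

## The problem

Bulk genomics of tumors mostly reads out the cancer cells and misses the
stroma. Decellularizing tissue before mass spectrometry enriches the
extracellular matrix (ECM), so the resulting protein quantifications
describe the matrisome — collagens (COL), ECM glycoproteins (GLY),
proteoglycans (PRO), ECM regulators (REG), ECM-affiliated proteins (AFF)
and secreted factors (SEC). matriscope is for analysts working with such
data: it implements the full path from a multi-plex TMT intensity matrix
to histology-specific matrisome programs, their cellular origin in
single-cell data, and their prognostic value in bulk cohorts.

The core statistical machinery:

* **Two-stage TMT normalization.** Stage 1 centers each channel's log2
  intensities on a common median:
  `out[i,j] = 2^(log2(x[i,j]) − m_j + mean(m))`. Stage 2 bridges plexes
  on the pooled-control reference channel (R2, 131C):
  `out[i,j] = x[i,j] / x[i,R2(p)] · a_i` with `a_i` the protein's mean R2
  intensity across plexes.
* **Differential matrisome proteins (DEPs).** Fold change from
  linear-scale group means; Welch's t-test on log2 intensities; DEP iff
  `|log2FC| > 0.5` (FC > √2) and `p < 0.05` (raw p-values by design; BH
  optional). The PEM set is the PCC-NOS-enriched direction of the
  PCC-NOS vs non-PCC-NOS tumor contrast.
* **Cellular origin.** A gene's origin is the cell type with the highest
  average expression, granted only if the gene is cell-type-specific
  (one-vs-rest Wilcoxon, BH-adjusted p < 0.01, positive effect).
* **ssGSEA scoring.** A single-sample rank-enrichment running sum with
  rank^0.25 weights, one audited implementation for cells and bulk.
* **Survival.** Mean-split score groups, Kaplan–Meier curves, log-rank
  test.

A synthetic-data generator emulates the whole study design — five TMT
11-plexes (9 samples + 2 pooled references each; 19 TUM / 17 NAT / 5 LNM
/ 4 NN), log-normal intensities with plex batch effects, planted
tumor and PCC-NOS effects, a 7-cell-type single-cell cohort with a
planted fibroblast program, and a bulk cohort whose hazard follows a
planted gene-set score — so every stage is testable offline.

## Worked example

```r
library(matriscope)

report <- run_pipeline(pipeline_config(seed = 1))
report
#> <run_report>
#>   cohort: 4838 proteins (376 matrisome), 45 sample channels
#>   DEPs tumor vs NAT: 59 (29 tumor-, 30 NAT-enriched); PEMs: 27
#>   fibroblast origin fraction: 0.81; score correlation r = 0.968
#>   log-rank chi-squared = 68.36, p = 1.36e-16
```

Reading the numbers: the synthetic cohort reproduces the 45-sample,
five-plex design with 376 matrisome proteins among 4838. The tumor vs
NAT contrast calls 59 differential matrisome proteins at the FC > √2,
p < 0.05 rule (the generator plants 20 up and 30 down; the remainder are
borderline noise calls at raw-p thresholds). The PCC-NOS contrast
recovers exactly the 27 planted program proteins (the PEMs). In the
synthetic single-cell data, 81% of PEMs are assigned a fibroblast
origin, matching the planted 80% purity. On the bulk cohort the PEM
ssGSEA score correlates r = 0.97 with the adipogenic-CAF-marker score,
and the planted hazard makes the high-PEM-score group's survival
markedly worse (log-rank p ≈ 1e-16).

Individual stages compose with pipes:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
norm   <- normalize_quant(cohort$quant, cohort$design)
smp    <- dplyr::left_join(dplyr::filter(cohort$design, role == "sample"),
                           cohort$samples, by = "sample_id")
dep    <- welch_dep(norm,
                    smp$channel[smp$tissue == "TUM"],
                    smp$channel[smp$tissue == "NAT"],
                    annotation = cohort$annotation)
glance(dep)      # DEP counts and thresholds
autoplot(dep)    # volcano plot
```

See `vignettes/matriscope-methods.Rmd` for the model, parameter and
design choices, and `?generate_cohort`, `?welch_dep`, `?sc_score`,
`?km_estimate` for the individual stages.

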