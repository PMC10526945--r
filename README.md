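# cnvrscan

Copy number variation regions (CNVRs) — stretches of the genome deleted
or duplicated relative to the diploid reference — are a major source of
quantitative-trait variation in livestock. `cnvrscan` is an R package
for the full CNV association workflow used in extreme-phenotype designs,
with pig aggression as the motivating case: score a herd for behavior,
sequence the phenotypic extremes, call CNVRs from windowed read depth,
find the regions that differentiate the groups, and test whether a
candidate region drives gene expression through a dosage effect.

It is aimed at quantitative geneticists who want the statistical
machinery of such studies as reusable, tested functions — including a
synthetic cohort generator so every stage runs and is verifiable without
access to sequencing data.

## What it computes

* **Composite aggressive score (CAS)** per pig:
  `attack_count + 0.07 × attack_duration_s` over 72 h post-mixing, with
  deterministic selection of the most/least aggressive groups (MAP /
  LAP).
* **Copy number and CNVRs**: per-individual normalization
  `CN = 2·depth/median(depth)`, window typing at the inclusive
  thresholds `CN ≤ 1.5` (loss) / `CN ≥ 2.5` (gain), and assembly of
  maximal variant-window runs into loss / gain / both regions with
  carrier counts.
* **Landscape statistics**: counts by type, genome fraction, length and
  carrier-frequency histograms, chromosome-level regressions,
  cross-study interval overlap (≥ 1 shared bp, half-open coordinates),
  and positional annotation (Promoter > 5' UTR > 3' UTR > Exon >
  Intron > Distal Intergenic).
* **Differentiation**: the V_ST statistic
  `(V_total − (V_m·N_m + V_l·N_l)/N_total) / V_total` with top-1%
  flagging, and a mixed linear model
  `y = Xa + Wb + g + e`, `g ~ N(0, σ_g² K)`, fitted EMMA-style (exact
  REML on the null model via the eigendecomposition of the
  standardized-dosage kinship K, then per-region generalized least
  squares with Wald tests).
* **Dosage integration**: cis/trans eQTL (`expression ~ CN +
  covariates`, 1 Mb cis window, BH per relation class), qPCR 2^(−ΔCt)
  relative copy number with standard-curve efficiency, grouped
  t-tests, two-step validation and Mann–Whitney ROC/AUC.
* **A synthetic cohort generator** producing depth matrices, truth
  CNVRs, attack records, expression and qPCR plates with a causal
  CNVR at a target V_ST and a linear dosage effect — the fixture for
  the whole pipeline.

## Worked example

```r
library(cnvrscan)
res <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
```

The default configuration simulates a 48-pig herd, selects 12 + 12 CAS
extremes, and runs every stage on the sequenced 24. On seed 1 it calls
21 CNVRs; the causal region is recovered as `CNVR-5`:

```
head(res$vst, 3)
    name       vst rank top_1pct
  CNVR-5 0.4931045    1     TRUE      # realized V_ST at the causal region
  CNVR-4 0.1867832    2    FALSE
 CNVR-17 0.1647955    3    FALSE

res$gwas[order(res$gwas$p)[1:3], ]
    name      beta       se          p
  CNVR-5  4.268078 1.178898 0.00170557  # CAS units per copy
 CNVR-20 -2.520850 1.279841 0.06288532
  CNVR-4 -2.067449 1.568310 0.20231394

subset(res$eqtl, cnvr == "CNVR-5" & gene == "gene_causal")
   cnvr        gene   effect            p relation distance
 CNVR-5 gene_causal 1.144854 8.750723e-07      cis        0

res$validation$roc$auc
[1] 0.875
```

Read: the causal CNVR is top-ranked by both V_ST and the mixed-model
scan; its copy number raises CAS by ~4.3 points per copy and the
overlapping gene's expression by ~1.1 log2 units per copy (simulated
truth: 0.8, within the standard error); as a diagnostic marker for
group membership its AUC is 0.875. The two-step validation (extremes
compared on copy number, and both median-split variants) is in
`res$validation$two_step`. Each stage also writes TSV/BED/JSON outputs
plus a provenance block under `run1/`, and re-running with the same
seed reproduces them byte for byte.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --out-dir run1 --seed 1
```

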