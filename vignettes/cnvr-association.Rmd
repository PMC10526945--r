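---
title: "CNVR detection and dosage-effect association with cnvrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNVR detection and dosage-effect association with cnvrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrscan)
```

## The analysis in one paragraph

Copy number variation regions (CNVRs) — genomic intervals deleted or
duplicated relative to the diploid reference in at least one individual —
are a substantial source of quantitative-trait variation in livestock.
`cnvrscan` implements a complete desk-scale version of a CNV association
design used to study aggressive behavior in weaned pigs: a herd is scored
for aggression after mixing, extreme-phenotype groups are selected for
sequencing, per-window read depth is converted to copy number and
segmented into typed CNVRs, regions are ranked by between-group
differentiation (V\_ST) and by a kinship-corrected mixed-model
association with the behavioral score, candidate regions are linked to
gene expression through a dosage eQTL, and the surviving marker is
validated with qPCR relative copy numbers, grouped t-tests and ROC
analysis. Because such studies rarely release raw reads, the package
pairs every analysis stage with a synthetic cohort generator that
reproduces the statistical structure the design assumes, so the entire
pipeline is testable end to end.

## Phenotype: the composite aggressive score

Aggression is summarized per pig over 72 h post-mixing as a composite
aggressive score,

$$\mathrm{CAS} = \text{attack count} + 0.07 \times \text{attack duration (s)},$$

so one second of fighting counts 7% of one initiated attack. The inputs
are pre-aggregated counts and durations; bout-detection rules used
during video scoring are observational protocol, not computation, and are
out of scope. Groups are the CAS extremes: the most aggressive pigs
(MAP) and the least aggressive pigs (LAP). Ties are broken by pig id so
selection is deterministic and permutation-invariant; a median-split
variant (`n_top = ceiling(n/2)`) serves the two-step validation.

```{r}
composite_aggressive_score(12, 60)
```

## Copy number and CNVR assembly

Windowed read depth (800-bp windows by default, the convention of
read-depth CNV callers) is normalized per individual: copy number is
`2 * depth / median(depth)`, anchoring each pig's genome-wide median at
diploid. Window copy numbers classify as **loss** (≤ 1.5), **normal**
(1.5–2.5, exclusive) or **gain** (≥ 2.5); the boundaries belong to
loss/gain because those thresholds are the inclusively stated ones. A
window is *variant* when at least `min_carriers` pigs are non-normal;
maximal runs of variant windows (optionally tolerating short gaps)
become CNVRs, dropped when shorter than `min_length` (default 1500 bp,
i.e. ≥ 2 windows). A region showing only losses is a loss CNVR, only
gains a gain CNVR, and both a "both" CNVR. Regions are named
`CNVR-<k>` in chromosome-position order.

This is deliberately a simplified read-depth caller: GC and mappability
correction, duplicate-window merging and correlation-based genotyping of
production CNV callers are not reproduced (the generator simulates no
GC bias, so tests cannot exercise them), and the X chromosome is treated
as diploid. Results on real data will differ from a production caller's;
the caller here exists so that segmentation, typing and everything
downstream are fully specified and testable.

## Differentiation: V_ST and the mixed model

Between-group differentiation per CNVR is

$$V_{ST} = \frac{V_{total} - (V_m N_m + V_l N_l)/N_{total}}{V_{total}},$$

with $V_{total}$ the pooled copy-number variance and $V_m, V_l$ the
within-group variances. Variances are population (divide-by-N) by
default so that two internally constant, distinct groups give exactly 1
and identical groups 0; a sample-variance mode is available
(`estimator = "sample"`). Undefined values (zero pooled variance) are
reported missing, never as 0, and slightly negative finite-sample values
are preserved. The scan flags the top 1% — `floor(0.01 * n)` regions, at
least one — with ties broken by region name.

The association scan fits, per CNVR,
`CAS = covariates + b * copy_number + polygenic + residual` with the
polygenic term covarying as $\sigma_g^2 K$. K is a standardized-dosage
genomic relationship matrix over the CNVR copy numbers ($K = ZZ'/m$,
diagonal mean exactly 1). The variance ratio is estimated once by exact
REML through the eigendecomposition of K (the EMMA strategy), then each
region is tested by generalized least squares with a Wald t-test — the
usual "population parameters previously determined" approximation, which
collapses exactly to OLS when K is the identity. A single global K is
used for all tests, matching the single-kinship design of the study this
emulates; leave-one-chromosome-out kinship was considered and not
implemented, because at the simulated genome sizes (tens of regions on a
few chromosomes) removing a chromosome distorts K far more than the
proximal-contamination it guards against. Copy numbers enter as
continuous dosages — read-depth estimates are continuous, and rounding
discards signal; for mixed loss/gain regions, where carriers move in
opposite directions, an absolute-deviation-from-2 coding is available
(`coding = "absdev"`), without any claim that it reproduces the original
analysis.

## Dosage eQTL, qPCR and validation

Each (CNVR, gene) pair is tested with
`expression ~ copy_number + covariates`; pairs are *cis* when the gap
between the region and the gene's transcript span is at most 1 Mb
(configurable — the source design names cis/trans but no distance, and
1 Mb is the common cis-eQTL window), *trans* otherwise.
Benjamini–Hochberg adjustment is reported within each relation class,
but ranking, not an FDR cutoff, drives the headline outputs, matching
the design. Expression is log2(x+1)-transformed by default; the
generator already emits log-scale values, so the pipeline runs its eQTL
stage with `log_transform = FALSE`.

qPCR relative quantity follows the 2^(−ΔCt) method with a single-copy
reference gene: ΔCt = Ct(target) − Ct(reference), relative quantity
2^(−ΔCt), and — as an explicitly separate field, since relative values
are what such studies plot — `calibrated_cn = 2 * 2^(−ΔCt)` converts to
an absolute copy number under the diploid-reference assumption. The
standard curve regresses Ct on log10 input; efficiency is
`10^(-1/slope) - 1`. Validation runs three grouped Student's t-tests
(pooled variance, Welch behind a flag): CAS extremes compared on copy
number, a copy-number median split compared on CAS, and a CAS median
split compared on copy number; with odd n the larger half is the top
half. ROC analysis evaluates the copy number as a diagnostic marker for
group membership; AUC is the Mann–Whitney statistic with ties counted
1/2, which equals the trapezoidal area under the returned curve.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the analysis assumes:

* a herd of 48 pigs (a down-scaled stand-in for selection from a large
  herd) scored for CAS, from which 12 MAP + 12 LAP are "sequenced";
* per-pig mean depth uniform in 10–16×, mimicking typical resequencing
  depth ranges, with window depth Gaussian around
  `mean_depth * CN / 2` (SD = `depth_noise_sd * mean_depth`, truncated
  at 0) — the simplest error model that exercises the normalization
  path, as no error model is published;
* background loss/gain/both CNVRs (integer carrier copy numbers,
  random carrier frequencies) on a small 4-chromosome genome
  (120/100/80/60 kb in 800-bp windows; sizes chosen so a full cohort
  simulates in well under a second while every stage still has tens of
  regions to rank);
* one causal gain-like CNVR whose copy number forms two balanced latent
  clusters `N(2, s)` vs `N(2 + d, s)`, with CAS generated as
  `baseline + 3 * (CN - 2) + sex/batch effects + noise` (a ~1.5
  residual-SD effect per copy) and then decomposed into attack counts
  (Poisson) and durations so the CAS arithmetic is exercised end to
  end;
* expression for the gene over the causal region following
  `base + 0.8 * CN + N(0, 0.5)` on a log2-like scale, all other genes
  independent of copy number; and a qPCR plate with
  `ΔCt = -log2(CN/2) + N(0, 0.1)`.

The cluster separation `d` is not the naive
`2s\sqrt{t/(1-t)}` implied by a target V\_ST of `t`: selecting CAS
extremes mixes the latent clusters (deflating differentiation) and
selects on copy number within clusters (inflating it). The generator
therefore calibrates `d` once per configuration by bisection against a
Monte-Carlo estimate of the realized post-selection V\_ST (200
replicates, common random numbers, a fixed internal RNG stream), and
caches the result. Requesting a target below what CAS selection alone
induces, or a target of 1 with nonzero within-group SD, is refused with
an explanatory error. Truth CNVRs are defined with respect to the
sequenced cohort — a region whose carriers were all left unsequenced is
not a truth region, and its loss/gain/both label reflects the sequenced
pigs' values — since that is the population every downstream stage sees.

What the generator does **not** emulate: GC and mappability bias,
read-level artifacts, linkage between regions, non-Gaussian depth
noise, pen effects on behavior beyond a fixed covariate, and real
chromosome-scale genome structure. Passing tests therefore demonstrate
the statistical machinery is correct under the assumed model, not that
the caller matches production callers on real sequencing data.

## Numerical choices

* One master seed drives documented sub-streams (genome/regions,
  phenotypes, depth, gene models, expression, qPCR), so cohorts are
  bit-reproducible.
* REML maximizes over `log(delta)` on [−5 log 10, 5 log 10] by Brent
  search; eigenvalues of K are clipped at 0; the per-marker residual
  variance is re-estimated with `n - p - 1` degrees of freedom for the
  Wald t-test.
* Zero-variance markers (kinship, GWAS, eQTL) are dropped or skipped
  with a recorded reason rather than producing NaNs; zero pooled
  variance makes t-tests and V_ST return NA.
* Interval arithmetic is 0-based half-open everywhere internally and in
  BED output; GFF3 input converts from 1-based inclusive. Overlap means
  sharing at least 1 bp, so abutting half-open intervals do not overlap.
* The promoter window is 2000 bp upstream / 500 bp downstream of the
  TSS (a common annotator default; only the category name is fixed by
  the emulated design), strand-aware, and positional categories resolve
  by the priority Promoter > 5' UTR > 3' UTR > Exon > Intron > Distal
  Intergenic, so the categories partition any region set. Joint "3' and
  5' UTR" reporting (`split_utr = FALSE`) mirrors figure conventions
  that pool the UTRs.
* Carrier-frequency histogram bins default to 1–4, 5–10, 11–15, 16–20,
  >20 pigs — contiguous 5-wide bins consistent with the two named bins
  of the emulated report — and length bins to <5, 5–10, 10–100,
  >100 kb, half-open on the left edge.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
res$report$vst$top        # top-ranked region by V_ST
res$report$gwas$top       # top association hit
res$report$qpcr_roc$auc   # marker AUC in the validation stage
```

Every stage writes TSV/BED/CSV/JSON outputs plus a provenance block
(parameters, seed, output checksums) under the output directory, and
re-running with the same seed reproduces the tables byte for byte.

## Problem sizes used by the checks

The package's own test suite and the `scripts/acceptance.R` report use
20 replicate cohorts for recovery and caller-fidelity rates, 20 × 500
null regions at n = 24 for mixed-model calibration, 10^4 random group
pairs for the V_ST oracle, and 10^3-draw Monte-Carlo checks for the
qPCR and expression generators — sizes chosen so the whole suite runs
in a couple of minutes on one core while keeping Monte-Carlo standard
errors well inside the asserted tolerances.

## Known limitations

The caller is a stand-in, not a re-implementation, of production
read-depth CNV callers; kinship from CNVR dosages differs from a
SNP-thinned kinship and is documented as a departure; sex chromosomes
are treated as diploid; and no multiple-testing threshold is imposed on
the association scan (the emulated design reports ranks and raw
p-values). Real-data coordinates of published candidate loci are not
asserted anywhere — the interest is in the machinery, which is fully
specified here.
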