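---
title: "Pothole and molehill analysis of white-matter FA: methods and design"
author: "potholes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pothole and molehill analysis of white-matter FA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potholes)
```

## The model

Fractional anisotropy (FA) is a scalar in [0, 1] derived from the diffusion
tensor; it is high where white-matter fibers are coherently organized and
falls where microstructure is disrupted. Given a cohort of spatially aligned
FA volumes, the analysis asks a simple question at every voxel: how unusual
is this subject here, relative to the cohort?

Concretely, for voxel $v$ and subject $i$,

$$z_i(v) = \frac{\mathrm{FA}_i(v) - \bar{\mathrm{FA}}(v)}{s(v)},$$

where $\bar{\mathrm{FA}}(v)$ and $s(v)$ are the cohort mean and sample SD at
that voxel. Analysis is restricted to a white-matter mask: voxels whose
cohort mean FA strictly exceeds 0.2 (and whose SD is strictly positive, so
$z$ is finite). A **pothole** is a maximal contiguous cluster of voxels with
$z < -2$; a **molehill** is the mirror-image cluster with $z > +2$. Because
white-matter lesions vary widely in size, clusters are profiled at an
increasing ladder of volume cutoffs — retained when their volume strictly
exceeds 25, 50, 100 and 200 mm³ — and the per-subject counts at each rung
are the phenotypes carried into the statistics.

Downstream, each subject's counts are modeled by ordinary least squares
against sex, age and a polygenic risk score (PRS), with false-discovery-rate
control within each family of tests. The PRS is the classical thresholded
additive score: over variants whose discovery GWAS p-value is strictly below
$P_T$ (default 0.01), sum dosage × effect size, then standardize to mean 0,
SD 1.

## Pipeline stages and their parameters

| Stage | Parameter | Default | Meaning |
|---|---|---|---|
| mask | `faThreshold` | 0.2 | cohort-mean FA cutoff (strict `>`), the conventional white/gray boundary for FA |
| clusters | `zThreshold` | 2 | deviation cutoff in SD units (strict on both tails) |
| clusters | `connectivity` | 26 | voxel adjacency (6 faces, 18 +edges, 26 +corners) |
| clusters | `volumeThresholds` | 25, 50, 100, 200 mm³ | cluster-size ladder (strict `>`) |
| tracts | `rule` | plurality | cluster-to-tract assignment |
| score | `pThreshold` | 0.01 | GWAS p-value inclusion cutoff (strict `<`) |
| score | `excludeRegions` | none; `mhcRegion()` available | half-open [start, end) intervals |

Several conventions deserve a word:

* **Strict inequalities everywhere.** The mask uses mean FA *greater than*
  0.2, clusters use $z > 2$ / $z < -2$, the size filter keeps volume
  *greater than* the cutoff, and the score keeps p *less than* $P_T$. Each
  comparison is configurable to its inclusive form (`inclusive = TRUE`,
  `wmMask(..., faThreshold = )`) for sensitivity analyses, but the strict
  form is the default and the tested contract.
* **Connectivity.** 26-connectivity is the default, the common choice for
  cluster thresholding in neuroimaging; 6 and 18 are selectable and recorded
  in the run manifest. The choice matters at cluster boundaries: two voxels
  touching only at a corner are one cluster under 26 and two under 6.
* **Voxel volume comes from the header.** Cluster volume is voxel count ×
  voxel volume from the image geometry, never an assumed constant, so
  anisotropic grids are handled correctly.
* **Sample SD with the $n-1$ denominator**, configurable to $n$. Each
  subject contributes to the reference used for its own z-map; an optional
  leave-one-out mode (`cohortZMaps(leaveOneOut = TRUE)`) recomputes each
  subject's reference from the other $n - 1$ subjects. With cohorts of 50+
  the two differ negligibly, which is why the simpler all-subjects
  reference is the default.
* **Voxels with zero SD are excluded from the mask** rather than producing
  infinite z-values.
* **Deterministic output order.** Clusters are sorted by descending volume,
  ties broken by the lexicographically smallest voxel coordinate, so output
  tables are byte-identical across reruns.

## Tract assignment

Clusters are localized against an integer-labeled tract atlas on the cohort
grid. The default *plurality* rule gives each cluster to the single label
owning the most of its voxels (ties to the lowest label id; no overlap at
all means "unassigned"). This keeps each cluster counted exactly once, so
per-tract counts plus the unassigned remainder decompose the global count —
an invariant the tests enforce. The alternative `any_overlap` rule credits
every overlapped tract and is useful descriptively, but breaks the
decomposition; outputs record which rule produced them.

The package ships a 17-label toy atlas (`toyTractAtlas()`): one midline
corpus-callosum-like region and eight left/right tract pairs, mirroring the
17-test tract analysis the association suite runs. Any user-supplied labeled
NIfTI atlas on the cohort grid is accepted via `readTractAtlas()`.

## Association suite

Three FDR families are fit, mirroring how such analyses group their tests:

* **Descriptive (16 tests):** sex and age against each polarity × size
  threshold, each exposure adjusted for the other; BH-FDR over all 16.
* **Genetic (8 tests):** the standardized PRS against each polarity × size
  threshold, adjusted for age, sex and the first 10 genetic principal
  components; FDR over the 8.
* **Tract (17 tests):** one model per tract at a chosen polarity/threshold,
  with a handedness covariate added only for lateralized (left/right)
  tracts; FDR over the 17.

Counts are modeled on their natural scale by OLS, so betas are in count
units per exposure unit; the "scaled β" for the PRS means the *exposure* is
standardized while the outcome is not. A fully standardized variant
(`standardizeOutcome = TRUE`) and a log-link Poisson sensitivity fit
(`family = "poisson"`) are provided, but the OLS-on-counts form is the
default and the one the acceptance surface exercises. ΔR² is the
variance-explained increment of the full over the exposure-dropped model,
fit on identical rows (listwise deletion of missing data; no imputation).
Sex is coded female = 1 / male = 0, so a negative sex beta means fewer
anomalies in girls.

One caution from the engine's own geometry: cluster counts are *not*
monotone in the z-threshold. Raising the cutoff can split one large cluster
into several that each still clear a volume threshold, so counts can rise.
Counts are monotone non-increasing along the volume ladder, and that is the
invariant the tests assert.

## The synthetic cohort generator

No public FA cohort accompanies this method, so the package generates its
own, with ground truth:

* a deterministic **template**: box-shaped tracts with baseline FA 0.40–0.56
  on a 0.08 background, matching the toy atlas exactly;
* independent voxel-wise Gaussian **noise** per subject (default SD 0.02 FA
  units), clipped to [0, 1];
* **planted anomalies**: contiguous voxel sets grown inside the
  template's FA > 0.2 region, shifted by ±`magnitude` × noise SD
  (potholes down, molehills up). Magnitudes are expressed in noise-SD units
  so the expected z of a planted voxel is ≈ ±magnitude — this is what makes
  detection guarantees statable. Plants slightly perturb the cohort
  reference they are later judged against; at the default magnitude 6 with
  100 subjects, planted-voxel z remains far beyond the ±2 threshold, and
  the perturbation is negligible;
* **genotypes** as Binomial(2, MAF) dosages with a GWAS-style weights table
  (ID, CHR, BP, BETA, P), and a **covariate table** (age 9–12 y, sex
  Bernoulli(0.5), 10 standard-normal PCs, handedness Bernoulli(0.9),
  maternal education);
* a **score-linked anomaly rate**: each subject's molehill count is drawn
  Poisson(λ₀ + b·score) — a linear rate link rather than the canonical log
  link, deliberately, so the linear-regression suite that estimates the
  effect is correctly specified for the process that generated it; negative
  rates are truncated at zero (or rejected if truncation is disabled);
* an optional score-independent **background anomaly process** of both
  polarities (`bgPotholeRate`, `bgMolehillRate`), emulating the substantial
  anomaly load every subject carries regardless of risk; the demo pipeline
  uses rate 3 per polarity so no count outcome is degenerate.

The default demo conditions are 100 subjects on a 32³ grid of 2 mm voxels —
large enough that plant density stays near 3% of the eligible mask. On much
smaller grids heavy planting saturates the template regions, inflates the
reference SD, and erodes detection; the pipeline tests therefore use 24³,
not 16³, for full runs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial autocorrelation of FA noise (real
smoothness raises large spurious-cluster rates well above the independent
-noise case), registration error, tract geometry beyond axis-aligned boxes,
linkage disequilibrium between variants, and any true sex/age effect on
anomaly counts. The effect-recovery simulations size the score effect to
explain ≈0.85% of count variance at n = 1000 — the magnitude regime such
cohort analyses report — giving analytic power near 0.83 at α = 0.05, which
is why the recovery check asks for ≥80% over 100 replicates.

## Numerical and testing choices

* Connected components are labeled by breadth-first flood fill over a
  zero-padded grid; the test suite checks the partition against an
  independent minimum-label-propagation oracle on hundreds of random grids
  for all three connectivities, which also establishes that the result does
  not depend on voxel processing order.
* BH-FDR is computed by `stats::p.adjust(method = "BH")` behind input
  validation; tests compare it against a from-the-definition step-up
  implementation on 1000 random p-vectors.
* z-maps built from the same cohort as their reference have, at every
  masked voxel, cross-subject mean exactly 0 and sample SD exactly 1; the
  suite asserts this to 1e-10, which doubles as a regression guard on the
  SD denominator.
* Problem sizes in the test and acceptance runs (50–100 subjects, 24³–32³
  grids, 100–500 regression replicates) were chosen as the smallest sizes
  at which the statistical properties under test are stable; all
  simulations are seeded and bit-reproducible, including the full demo
  pipeline (`runPipeline()` writes a manifest with parameters, seed and
  output digests).

## Known limitations

* No spatial registration: volumes must arrive pre-aligned on one grid.
* No LD clumping or allele harmonization in the score engine; weights are
  assumed pre-pruned and dosages pre-harmonized to the effect allele. The
  extended-MHC default of `mhcRegion()` (chr6:25–35 Mb) is a convention,
  not a reproduction of any particular study's bounds.
* Independent voxel noise in the generator, as discussed above.
* OLS on counts can in principle predict negative counts; the Poisson
  option exists for exactly that sensitivity check.
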