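---
title: "Methods: PET texture analysis, outcome association, and the synthetic cohort"
author: "pettex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET texture analysis, outcome association, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pettex)
```

## The problem

Early-stage non-small cell lung cancer treated with stereotactic body
radiotherapy (SBRT) achieves high local control, but a minority of tumors
recur locally, and identifying them on follow-up imaging is confounded by
radiation-induced changes. Intratumoral heterogeneity of FDG uptake on the
*pre-treatment* PET scan is a candidate prognostic marker: a tumor whose
uptake pattern is spatially disordered may harbor biology (hypoxia,
heterogeneous perfusion) associated with radioresistance. `pettex`
implements the full measurement-and-association chain for this question:
tumor segmentation on SUV images, conventional and textural feature
extraction, and the statistical battery relating features to recurrence
and survival, together with a synthetic cohort generator that makes every
stage testable without patient data.

## Segmentation

The volume of interest (VOI) is the connected component of the
supra-threshold set $\{x : \mathrm{SUV}(x) \ge T\}$ that contains the
hottest voxel, with $T = 2.0$ as the primary definition and $T = 2.5$ for
the stability comparison. Design choices the isocontour convention leaves
open, and how this package resolves them:

* **Connectivity.** The 26-neighborhood is the default (a diagonal bridge
  keeps a lesion connected); 6 and 18 are available because component
  membership genuinely changes with connectivity.
* **Closed threshold.** A voxel exactly at $T$ is inside the VOI
  (`SUV >= T`).
* **Manual correction.** Interactive contour editing is replaced by an
  `override` mask accepted verbatim at the interface.
* **Coordinates** are 1-based voxel indices; physical spacing enters only
  where volume is needed.

Because the seed voxel is by construction inside its own component,
SUV~max~ over the VOI is *exactly* invariant to the threshold — the basis
of the `r = 1` stability row that the acceptance script reproduces.

## Features

Four conventional metrics are computed on floating-point SUV values:
SUV~max~, SUV~mean~, metabolic tumor volume
$\mathrm{MTV} = n_{\mathrm{vox}} \cdot v_{\mathrm{vox}} / 1000$ (ml), and
the coefficient of variation $\mathrm{COV} = \sigma / \mu$ with the
population SD.

For texture, VOI values are min–max resampled to $B = 64$ gray tones,

$$R(x) = B\,\frac{I(x) - \mathrm{SUV}_{\min}}{\mathrm{SUV}_{\max} - \mathrm{SUV}_{\min}},
\qquad \mathrm{bin}(x) = \mathrm{clamp}(\lfloor R(x)\rfloor + 1,\ 1,\ B),$$

so the VOI minimum maps to bin 1 and the maximum into bin 64; a flat VOI
maps entirely to bin 1. The floor-plus-clamp rule is this package's
choice; the resampling equation itself fixes only $R(x)$.

**GLCM.** Co-occurrences of gray-tone pairs at unit voxel offset are
counted along the 13 unique 3D directions (the nonzero offsets of
$\{-1,0,1\}^3$ modulo sign), symmetrized by adding the transpose, pooled
across directions (`merged`, the default) or averaged per direction, and
normalized. Offsets are one voxel in *index* space; with 4.06 mm in-plane
and 5.0 mm axial spacing the 13 physical step lengths differ by up to
70%, a bias inherent to pure matrix methods on anisotropic grids and
documented rather than corrected. From the joint distribution $p(i,j)$:

* entropy $-\sum p \log_2 p$ (bits; the base is configurable and recorded
  in the output),
* contrast $\sum (i-j)^2 p(i,j)$ (bin²),
* correlation $\sum (i-\mu)(j-\mu)p(i,j)/\sigma^2$ with marginal moments
  (the marginals coincide by symmetry). When $\sigma = 0$ (single
  occupied level) correlation is defined as 1, with a warning.

**NGTDM.** For each VOI voxel with at least one in-mask 26-neighbor, the
neighborhood mean gray tone is computed over in-mask neighbors only — the
VOI boundary is tissue, not an image border, so no padding is used. With
$s_i$ the summed deviations $|i - \bar A_i|$ at level $i$ and $p_i$ the
level occupancy,

$$\text{coarseness} = \Big(\varepsilon + \sum_i p_i s_i\Big)^{-1},\qquad
\text{busyness} = \frac{\sum_i p_i s_i}{\sum_{i \ne j} |i\,p_i - j\,p_j|},$$

with $\varepsilon = 10^{-6}$, coarseness capped at $1/\varepsilon$ for a
perfectly uniform VOI, and busyness defined as 0 when a single level is
occupied. These are the classical Amadasun–King forms; vendor
implementations are known to rescale them, so absolute values are not
comparable across software even when rankings are.

## Outcome statistics

* **ROC.** AUC is the Mann–Whitney statistic (ties one half); the 95% CI
  uses DeLong's distribution-free method (Hanley–McNeil available as an
  option). The operating cutoff minimizes the Euclidean distance
  $\sqrt{(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2}$ to the upper-left
  corner, ties broken toward higher specificity.
* **Survival.** Kaplan–Meier product-limit curves, two-sample log-rank
  test, and both median (first time $S \le 0.5$) and restricted mean
  survival are always reported, since "mean survival" conventions differ
  across reports.
* **Cox.** Partial likelihood with Efron tie handling; Wald 95% CIs.
  Multivariate models are restricted to three covariates — a deliberate
  guard for cohorts with around a dozen events. MTV enters on the log
  scale by convention. Non-convergence and separation raise diagnostics
  rather than returning silent estimates.
* **Dichotomization** of a feature for survival analysis uses the
  ROC-optimal cutoff against the corresponding event label. All tests are
  two-sided at the 5% level; no multiplicity correction is applied in the
  report tables (each row is flagged, not adjusted).

The study driver `runStudy()` additionally evaluates local recurrence
inside the T2 subgroup (diameter > 30 mm), because tumor size itself
predicts local failure and the scientific question is whether texture
carries information *beyond* size. "Cumulative dose" — a real covariate in
clinical multivariate models — has no phantom counterpart, so the
pipeline substitutes a declared, independently drawn value on the 24–45
Gy range; being independent of outcome, it behaves as a null covariate.

## The synthetic cohort

`generateTumorPhantom()` builds one lesion: an ellipsoid of the requested
physical diameter on the 4.06 × 4.06 × 5.0 mm grid, mean SUV
`tumorMeanSuv`, plus a spatially correlated Gaussian random field
(white noise smoothed with a Gaussian kernel of SD
`heterogeneityLengthMm`, renormalized to zero mean and SD
`heterogeneityAmplitude` over the tumor), embedded in uniform lung
background, optional i.i.d. voxel noise, and a clip at SUV 0.

Two numerical facts shaped the defaults:

1. **Min–max discretization is affine-invariant.** Scaling a noise-free
   texture field changes no bin assignment, so the *amplitude* of a
   noise-free texture does not move the texture features; what moves them
   is the field's spatial roughness. The cohort generator therefore
   varies the **correlation length** (4–14 mm) across patients as the
   primary heterogeneity driver, and the default `noiseSd` is 0. With
   additive i.i.d. noise the joint co-occurrence entropy *decreases* as
   the correlated field grows relative to the noise (correlated pairs
   replace independent ones), so a noisy default would invert the
   intended "more amplitude, more entropy" ordering; with the noise-free
   default, mean entropy is exactly non-decreasing in amplitude (zero for
   a flat tumor, constant above).
2. **Amplitude interacts with the segmentation threshold.** Per-patient
   amplitude is capped at `(tumorMeanSuv - 2.6)/3` so 3-SD dips stay
   above the 2.5 isocontour and both VOI definitions always find the
   lesion.

Cohort-level defaults emulate the clinical setting this analysis
addresses: diameters log-normal truncated to 17–68 mm (so both T1 and T2
tumors occur), tumor mean SUV uniform on 4.5–13, background 0.5.
Outcomes follow the assumed statistical structure: local recurrence is
Bernoulli with a logistic link on mean-centered entropy (base rate 7/45),
disease-specific death is exponential with a log-linear hazard in entropy
(baseline 0.012/month), an independent 0.015/month comorbidity clock
produces the texture-free deaths that dominate overall survival, and
censoring is uniform on 3–72 months. Nodal and distant recurrence are
drawn at rate 11/45 independent of texture. The recurrence *time* is not
part of the assumed structure and is filled in as a uniform 0.3–0.9
fraction of the observed survival time.

What the generator does **not** emulate — and what green tests therefore
do not establish about patient data: respiratory-motion blurring, scanner
PSF and reconstruction texture, partial-volume effects at the tumor rim,
lobulated or necrotic lesion shapes, and any real joint distribution
between uptake, size and biology. The phantoms validate the *machinery*
(segmentation, matrices, statistics), not clinical effect sizes. One
concrete artifact: because the field is renormalized over tumor voxels,
phantom COV is almost a deterministic function of voxel count, so
phantom-based size-dependency correlations for COV are not evidence about
patients.

## Numerical choices and degenerate inputs

* Flat VOI: all bins 1; entropy = contrast = 0; correlation defined 1
  (warning); busyness 0; coarseness at its 10⁶ cap; COV 0.
* A lesion entirely below threshold raises an explicit "no lesion at
  threshold" error, mirroring a non-avid lesion.
* Log-rank with zero events reports `NA` rather than a NaN statistic.
* Component growth is iterative masked dilation, verified against a
  breadth-first flood fill; GLCM/NGTDM are verified against triple-loop
  enumeration on random grids.
* Determinism: every generator is a pure function of (parameters, seed);
  a study run writes byte-identical reports under a fixed config, and the
  provenance block records seed, config hash and package version.

## Problem sizes used in the shipped checks

The test suite exercises phantoms of 16–24 voxels per side (diameters
17–56 mm), cohorts of 5–45, a 120-patient cohort for the planted-effect
multivariate recovery, 500-replicate calibration loops for log-rank
uniformity and the 5% null rejection rate, and n = 1000 parameter
recovery for Cox regression — sizes at which Monte-Carlo error is small
relative to the asserted tolerances while the whole suite stays fast.

## Known limitations

Only NIfTI volumes already in SUV units are ingested; DICOM conversion
(dose, decay, weight) must happen upstream. The feature set is
deliberately the nine parameters above, not the wider radiomics zoo, and
no IBSI conformance is claimed: published coarseness/busyness ranges from
vendor tools differ from the classical definitions implemented here, so
cross-software comparisons should use ranks or within-study correlations,
not absolute values.
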