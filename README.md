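# pettex

Textural analysis of FDG-PET tumor volumes and its association with
recurrence and survival — aimed at nuclear-medicine and radiation-oncology
researchers studying whether intratumoral heterogeneity on the
*pre-treatment* scan predicts outcome after stereotactic body
radiotherapy (SBRT) in early-stage non-small cell lung cancer, and at
methodologists who need a fully testable reference implementation of the
measurement chain.

## What it computes

Given a body-weight-normalized SUV volume, the tumor VOI is the connected
component of {SUV ≥ T} containing the hottest voxel (T = 2.0 by default,
2.5 for stability analysis). On the VOI, nine parameters are extracted:

* **Conventional:** SUV\_max, SUV\_mean, metabolic tumor volume
  MTV = n\_vox · v\_vox/1000 (ml), and COV = σ/μ.
* **Textural**, after 64-bin min–max resampling
  R(x) = 64·[I(x) − SUV\_min]/[SUV\_max − SUV\_min]:
  from the 13-direction 3D gray-level co-occurrence matrix p(i,j) —
  entropy −Σ p log₂ p, correlation Σ(i−μ)(j−μ)p/σ², contrast Σ(i−j)²p;
  from the 26-neighborhood gray-tone difference table (p\_i, s\_i) —
  coarseness [ε + Σ p\_i s\_i]⁻¹ and busyness
  Σ p\_i s\_i / Σ\_{i≠j} |i·p\_i − j·p\_j| (Amadasun–King).

Association machinery: ROC with DeLong CIs and the distance-to-corner
optimal cutoff, Kaplan–Meier/log-rank on cutoff-dichotomized groups, and
univariate plus restricted (≤ 3 covariate) multivariate Cox regression
with Efron ties, across the endpoints local recurrence (whole cohort and
the T2 subgroup, diameter > 30 mm), nodal and distant recurrence,
disease-specific and overall survival — plus feature-stability
correlations between the 2.0 and 2.5 isocontours and size-dependency
correlations against MTV. A synthetic generator (Gaussian-random-field
tumors on the clinical 4.06 × 4.06 × 5.0 mm grid, proportional-hazards
outcomes driven by entropy) stands in for patient data.

## Worked example

```r
library(pettex)

vol <- generateTumorPhantom(phantomParams(
  tumorDiameterMm = 30, tumorMeanSuv = 8,
  heterogeneityAmplitude = 1.2, heterogeneityLengthMm = 6, seed = 42))
extractAllFeatures(vol, thresholdSUV = 2.0)
#>  suv_max 10.1855   suv_mean 8.0000   mtv_ml 14.5056   cov 0.1496
#>  entropy 10.2872   correlation 0.6578   contrast 168.9530
#>  coarseness 0.0521  busyness 0.0103
```

The 30 mm sphere yields an MTV of 14.5 ml (analytic sphere volume
14.1 ml, the difference being voxelization), SUV\_mean equals the
requested tumor mean, and COV ≈ amplitude/mean. Entropy of 10.3 bits
(of a 12-bit maximum for 64 levels) reflects the short 6 mm correlation
length; a perfectly flat tumor would give entropy 0.

```r
r <- rocAnalysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
r
#> ROC: AUC 0.750 (95% CI 0.057-1.000), 2 pos / 2 neg
#>   optimal cutoff 0.6 (sens 0.500, spec 1.000)
```

AUC 0.75 is the pair-counting value (3 of 4 positive–negative pairs
correctly ordered); the cutoff 0.6 is the operating point closest to the
ideal (sens 1, spec 1) corner.

A full study — synthetic cohort, segmentation at both thresholds, all
five report tables, provenance — runs with:

```r
rep <- runStudy(studyConfig(nPatients = 45, seed = 1))
writeReport(rep, "study_out")   # 5 CSVs + report.json + study.log
```

## Documentation

The methods vignette (`vignettes/pet-texture-methods.Rmd`) documents the
model assumptions, every tunable parameter with its default and
rationale, what the phantom generator does and does not emulate, and the
numerical conventions for degenerate inputs.
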