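# PETstd

Landmark-based post-acquisition intensity standardization for PET
volumes, for imaging scientists who need activity-concentration (AC) or
SUV values to mean the same thing across subjects, scanners and sites.

PET voxel values drift multiplicatively with dose, uptake time, body
habitus, hardware and reconstruction; even SUV, which divides out dose
per body weight,

    SUV(v) = AC(v) / (injected dose / body weight),

leaves a several-fold spread in normal-organ uptake across a population.
`PETstd` implements a two-step remedy:

1. **Calibration (once per scanner/setup).** From a set of normal scans
   with a reference-organ mask (liver or spleen), find the upper
   percentile `β ∈ [90, 100]` minimizing the cross-subject coefficient
   of variation `δ_O(b) = σ_O(b) / m_O(b)` of standardized organ uptake;
   fix a standard scale `[s_min, s_max]` (0–50,000 for AC, 0–5 for SUV);
   estimate the standard median `s_m` as the mean of the per-image
   linearly mapped body medians; and estimate an inverse scale factor
   `λ⁻¹` as the reciprocal of the outlier-trimmed mean of the per-image
   scale factors.
2. **Transformation (each image, no masks needed).** Re-extract the
   image's landmarks `{min, p_α, p_m, p_β, max}` (body region by
   mean-thresholding, median and β-percentile within it) and apply
   `ψ = λ⁻¹ ∘ η`, where `η` maps `[p_α, p_m] → [s_min, s_m]` and
   `[p_m, p_β] → [s_m, s_max]` piecewise-linearly, extrapolating beyond
   `p_β` so hot spots are retained, never clipped.

The package also provides SUV conversion, iterative operation chains
(`s-AC → SUV → s-SUV`, ...), comparison baselines (Gaussian and z-score
reference-organ normalization, and the classic histogram-landmark
method), cohort metrics (cross-subject CV, test–retest mean normalized
difference, Welch t-tests between scanner cohorts), NIfTI/JSON I/O, a
command-line interface, and a deterministic synthetic PET phantom
generator used to validate everything end to end. See the vignette in
`vignettes/pet-intensity-standardization.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(PETstd)

cfg    <- phantomConfig(seed = 7)          # synthetic torso phantoms
cohort <- generateCohort(cfg, 30)
imgs   <- subjectImages(cohort)
masks  <- subjectMasks(cohort, "liver")

cvMetric(imgs, masks)                      # raw cross-subject spread
#> CohortMetrics [liver, n = 30]: M = 1.166e+04, S = 3669, CV = 31.47%

scale <- calibrate(imgs, masks)            # one-time calibration
scale
#> StandardScale (AC): sMin = 0, sM = 3.708e+04, sMax = 5e+04
#>   beta = 96.9, invScaleFactor = 0.2397, dx = 0.01

std <- lapply(imgs, standardize, scale = scale)
cvMetric(std, masks)
#> CohortMetrics [liver, n = 30]: M = 1.206e+04, S = 408, CV = 3.38%
```

The raw cohort's liver means vary by 31% because each subject carries
its own multiplicative gain; calibration places the upper percentile at
96.9 (just below the volatile hot-spot tail), and standardization
collapses the spread to 3.4% — the residual biological variation planted
in the phantom. Masks are needed only for calibration and evaluation;
`standardize()` itself is mask-free.

A thin command-line wrapper covers the same workflow from a shell:

```sh
Rscript inst/cli/petstd.R simulate  --n 20 --out subjects/ --seed 1
Rscript inst/cli/petstd.R calibrate --images subjects/ --organ liver \
        --modality AC --out scale.json
Rscript inst/cli/petstd.R apply     --scale scale.json \
        --in subjects/scanner1-S001/image.nii.gz --out std.nii.gz
Rscript inst/cli/petstd.R evaluate  --metric cv --images subjects/ \
        --organ liver --scale scale.json --out metrics.csv
```

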