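---
title: "Landmark-based intensity standardization for PET and SUV images"
author: "PETstd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based intensity standardization for PET and SUV images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PETstd)
```

## The problem

Voxel values in FDG-PET volumes — activity concentration (AC, Bq/ml) or
the standardized uptake value (SUV) derived from it — are not numerically
comparable across subjects, scanners, or sites. Dose, uptake time, body
habitus, reconstruction, and hardware all inject multiplicative and
distributional drift, so the same normal liver can read anywhere within a
several-fold intensity range. SUV, defined per voxel as

$$\mathrm{SUV}(v) = \frac{I(v)}{\text{injected dose} / \text{body weight}},$$

with dose in MBq, weight in grams, and an assumed tissue density of
1 g/ml, compensates only for dose and weight; substantial residual
variability remains. This package implements a post-acquisition
standardization: a one-time *calibration* learns a standard intensity
scale from a set of normal scans, after which a cheap per-image
*transformation* maps any scan — normal or pathological, no segmentation
needed — onto that scale, so that like tissues get like values.

## The model

### Landmarks

For an image $I$, five intensity landmarks anchor the mapping: the
whole-volume extrema $\min(I)$ and $\max(I)$, the lower-percentile value
$p_\alpha(I)$ (with $\alpha = 0$ this is $\min(I)$, the standard choice,
since PET backgrounds start at zero), the median $p_m(I)$ of the *body
region*, and the upper-percentile value $p_\beta(I)$ of the body region.
The body region is segmented by thresholding at the whole-volume mean:
PET histograms are bimodal (an air background mode near zero and a body
mode), and the mean falls in the valley. The median within the body is
insensitive to the roughness of this segmentation, which is why nothing
fancier (hole filling, morphology) is attempted. Voxels exactly at the
threshold are kept inside the mask, so constant images remain
non-degenerate at the masking stage.

`percentileOf()` fixes the percentile convention to linear interpolation
of order statistics at rank $1 + (n-1)q/100$ — the most common numeric
default — and the test suite pins it against an exhaustive
sort-and-interpolate oracle.

One point the landmark definitions leave open is the support over which
$p_\beta$ is taken. The body median is explicitly a body-region
quantity; we compute $p_\beta$ over the same body-mask support so that
both interior landmarks are independent of how much empty background the
field of view happens to contain. Using whole-volume support instead
would shift $\beta$ estimates slightly on images with unusual
background fractions.

### Calibration

Calibration uses $n \ge 3$ normal images plus a reference-organ mask
(liver or spleen — organs chosen for stable, uniform normal uptake) per
image. The upper percentile $\beta$ is the crux: too low wastes dynamic
range, too high lets volatile hot-spot intensities (tumors, bladder,
heart) contaminate the anchor. For each candidate $b$ on a grid over
$[90, 100]$ (step 0.1, matching the one-decimal precision at which
$\beta$ is conventionally reported):

1. landmarks are extracted at $b$ for every calibration image;
2. the standard median $s_m(b)$ is the mean over images of
   $\lambda_I(p_m(I))$, where $\lambda_I$ maps
   $[p_\alpha(I), p_b(I)]$ linearly onto $[s_{\min}, s_{\max}]$
   ($s_m$ is re-estimated for every candidate, since $\lambda_I$ depends
   on $p_b$; comparing coefficients of variation across $b$ would
   otherwise be ill-defined);
3. every image is mapped with the two-segment transformation below and
   the mean standardized intensity $\mu_O$ over the reference organ is
   recorded;
4. $\delta_O(b) = \sigma_O(b)/m_O(b)$, the cross-subject coefficient of
   variation of $\mu_O$.

Then $\beta = \arg\min_b \delta_O(b)$, with ties broken toward the
*largest* $b$ — the largest percentile whose CV is smallest. $\mu_O$ is
computed on the intermediate scale; the CV is invariant to the common
inverse-scale multiplier, so computing it after that multiplier would
change nothing (this is documented only for reproducibility).

The scale endpoints are fixed, not optimized: $s_{\min} = 0$ (PET minima
are essentially zero) and $s_{\max}$ defaults to 50,000 for AC and 5.00
for SUV. `chooseSMax()` implements the discriminability rationale behind
such defaults: any two intensities $dx$ apart should stay at least $dx$
apart after standardization, which holds exactly when both segment
slopes of the composed mapping are $\ge 1$ for every calibration image,
and the function returns the smallest candidate $s_{\max}$ achieving
that. The inverse-scale multiplier entering this criterion is supplied
as a fixed number (default 1, i.e. the criterion is applied on the
intermediate scale): if it were re-estimated per candidate it would
scale as $1/s_{\max}$ while the segment slopes scale as $s_{\max}$,
making the criterion independent of the candidate and therefore vacuous.
A fixed multiplier is the only self-consistent reading.

Finally the inverse scale factor: with $p_\alpha = 0 = s_{\min}$ each
$\lambda_I$ is a pure multiplier. Factors more than one sample SD from
their mean are discarded (a guard against outlier calibration scans), the
rest are averaged, and $\lambda^{-1}$ is the reciprocal of that mean. If
the exclusion would discard everything — possible only in degenerate
two-image sets — all factors are retained; the trimming rule is silent on
this case and the fallback is the least surprising completion.

### Transformation

The standardization $\psi = \lambda^{-1} \circ \eta$ is applied
per image, with landmarks re-extracted at the calibrated $\beta$. The
mapping $\eta$ has two linear segments: $[p_\alpha, p_m] \to
[s_{\min}, s_m]$ and $[p_m, p_\beta] \to [s_m, s_{\max}]$. The first
segment extends over $[\min(I), p_\alpha)$ — an empty interval when
$\alpha = 0$, but the branch is kept for general $\alpha$ — and the
second extrapolates over $(p_\beta, \max(I)]$, so hot-spot intensities
are *retained*, never clipped; the realized maximum $s'_{\max}$ varies
per image and is recorded in the provenance. $\eta$ is continuous at
$p_m$, strictly increasing, and exact at all three landmarks. The final
multiplication by $\lambda^{-1}$ restores physical magnitude.
Standardized volumes are written to disk as 32-bit floats with no
rounding or quantization.

Because all landmarks are positively homogeneous and $p_\alpha = 0$,
$\psi(cI) = \psi(I)$ voxelwise for any gain $c > 0$: the method removes
global multiplicative drift exactly. Chains of operations
(`applySequence()`) cover the iterative strategies s-AC → s-AC,
s-AC → SUV, SUV → s-SUV, etc.; each standardization step recalibrates on
the (already transformed) calibration set. AC volumes are assumed Bq/ml
on disk and converted internally to MBq/ml for the SUV formula.

### Evaluation metrics and baselines

* `cvMetric()` — cross-subject CV of per-image organ means
  ($S/M$, sample SD with $n-1$ denominator, as everywhere in the
  package);
* `mdMetric()` — test–retest mean normalized absolute difference,
  $\frac{1}{|P|}\sum |\mu_1 - \mu_2| / \frac{\mu_1 + \mu_2}{2}$, each
  term in $[0, 2]$;
* `interscannerCompare()` — two-sided two-sample t-test on organ means.
  Whether to pool variances is genuinely open; Welch is the default as
  the safer test under unequal cohort variances, with the pooled variant
  behind `varEqual = TRUE`.

Three comparison methods are included. Gaussian normalization divides
the volume by the per-image reference-organ SD; z-score normalization
first subtracts the calibration-set organ mean. Both require an organ
segmentation of every test image, which the landmark method does not.
The z-score output is centered near zero, so its cohort CV can be huge
or sign-flipped; method comparisons therefore use $|CV|$. The
histogram-landmark baseline (`nyulCalibrate()` / `nyulTransform()`) is
the classic two-step MRI scheme transplanted unchanged: foreground by
mean thresholding, landmarks at the deciles plus a fixed 99.8th upper
percentile, training by averaging landmark positions mapped onto a fixed
scale, transformation by piecewise-linear landmark matching. The 99.8th
percentile is the one upper anchor quoted for that method; its interior
landmarks are the customary deciles. This is a faithful reconstruction
of the cited scheme, not a reference implementation of the original
code.

## The synthetic phantom

No deposited PET data are used; the generator (`phantomConfig()`,
`generateSubject()` and friends) emulates exactly the statistical
structure the method relies on, so every claim in the test suite is
end-to-end computable.

Per subject, on a default $32^3$ grid: an ellipsoidal body occupying
half the volume (background fraction 0.5), background drawn as
$|N(0, 0.01 \cdot \text{bodyLevel} \cdot g)|$ so the volume minimum is
essentially zero; body tissue at $6000 g$ Bq/ml; ellipsoidal liver and
spleen with subject-level means drawn from $[7600, 8600]$ and
$[7000, 7900]$ Bq/ml times the gain $g$; and 2–5 hot-spot spheres at
3–10 × body level, placed inside the body but outside the named organs.
The per-subject gain $g \sim U[0.5, 2]$ models the combined
scanner/dose/habitus drift the method is meant to remove. Voxel noise is
truncated Gaussian with SD equal to `noiseCV` (default 0.12) times the
local tissue mean.

Rationale for the magic numbers:

* *Organ mean ranges × gain range* span roughly 3,500–17,200 Bq/ml,
  inside the published population range of normal liver/spleen AC
  (3,050–18,659 Bq/ml); with typical dose (450–650 MBq) and weight
  (49–98 kg) draws, organ SUVs land in the published 0.66–3.33 band.
* *Organs sit above the body's 90th percentile* so that the upper
  histogram region — where the optimized percentile must be placed and
  where the decile-anchored baseline interpolates toward its volatile
  99.8th-percentile anchor — is actually exercised.
* *Hot spots* are few, bright and highly variable (count, position,
  and multiplier all drawn per subject) to reproduce the volatile upper
  tail that makes a fixed high upper anchor fail on PET.
* *Within-organ heterogeneity*: each subject draws a multiplier
  $h \sim U[0.5, 2.5]$ on the organ noise CV. Real within-organ
  dispersion is not a fixed fraction of the organ mean; without this
  term the Gaussian/z-score baselines would be artificially perfect
  (dividing by an SD exactly proportional to the mean), which would
  misrepresent how such methods behave.
* *Repeat pairs* share the subject's biology, perturb organ means by a
  relative change with SD `repeatDeltaCV` (default 0.05, a realistic
  week-scale physiological drift), redraw the noise, and either share
  the gain (same scanner, default) or redraw it
  (`shareGain = FALSE`).

The generator is deterministic: every subject derives its own RNG
substream from (config seed, subject index), so cohorts are bit-identical
across calls and machines, and the caller's RNG state is left untouched.

What the phantom does *not* model: anatomy, attenuation and
reconstruction physics, partial-volume effects, spatially correlated
noise, and organ-segmentation error. Passing tests therefore demonstrate
the *algorithmic* properties of the method — gain invariance, correct
percentile optimization, metric behavior — under the distributional
assumptions stated above, not clinical performance on patient scans.

## Numerical choices and degenerate inputs

* Percentile convention: type-7 linear interpolation, pinned by an
  oracle test at $10^{-12}$.
* All SDs are sample SDs ($n-1$).
* Argmin ties in the percentile search go to the largest candidate.
* Constant images pass body masking (tie rule) but fail landmark
  extraction with a landmark-degeneracy error ($p_m = p_\beta$); all-zero
  images fail earlier with a degenerate-image error. Nothing collapses
  silently.
* Zero organ variance (Gaussian/z-score), zero cohort mean (CV), and
  zero pair sums (MD) raise explicit degeneracy errors; a t-test between
  two zero-variance cohorts returns $p = 1$ on equal means, 0 otherwise.
* Negative voxels are rejected at construction and at NIfTI read time.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 5–30 subjects
on $32^3$ grids (plus a 12-subject planted-cutoff cohort on $24^3$), with
the full percentile grid at step 0.1 for acceptance runs and a coarser
step 0.5 where only qualitative behavior is exercised. These sizes give
stable cohort statistics while keeping a full suite run under a minute;
all sizes scale up by configuration if sharper estimates are wanted.

## Known limitations

* Calibration quality is bounded by the normality of the calibration
  set; the scale-factor trimming guards against single outliers only.
* The method removes *global* multiplicative drift; spatially varying
  bias or additive offsets are out of scope.
* $\beta$ is optimized per reference organ separately; no joint
  multi-organ objective is provided.
* The body mask is intentionally crude; images whose background is not
  near zero (e.g. already-shifted data) violate its assumption.
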