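---
title: "Quantifying visceral adipose tissue from axial MRI: segmentation, landmark scaling and agreement"
author: "vatmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying visceral adipose tissue from axial MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vatmri)
```

## The problem

Visceral adipose tissue (VAT) -- the fat surrounding the abdominal organs --
is a metabolically active depot whose amount is a more informative risk
marker than BMI, with which it correlates only weakly.  Measuring the full
VAT volume requires segmenting fat on every axial slice between the pelvic
floor (PF) and the diaphragm (D), which is slow.  A practical surrogate is
the VAT area of one slice (or the sum over five adjacent slices) at an
anatomical landmark, converted to a volume estimate by a fixed scaling
factor.  This package implements that whole chain for morbidly obese
patients (BMI > 40 kg/m^2): histogram-threshold segmentation, PF-D
volumetry, through-origin scaling fits per landmark, gender and slice
count, and Bland-Altman agreement ranking of the landmarks, together with
a synthetic phantom and cohort generator that provides exact ground truth
for every stage.

## Segmentation model

Fat is bright on the source images, so each slice's abdominal-cavity ROI
is thresholded on signal intensity (SI).  The per-slice ROI histogram is
bimodal -- a lean-tissue peak at low SI, a fat peak at high SI, a local
minimum between them -- and the default threshold is placed **halfway
between the local minimum and the fat peak**; pixels with SI at or above
the threshold count as fat.  Experience with threshold positions closer
to the minimum shows they over-include lean tissue, which motivates the
halfway rule.  A manual per-slice override replaces the default wherever
the resulting overlay is judged wrong; every override is logged.

The histogram machinery makes several choices the threshold rule itself
does not fix:

* **256 bins** spanning the per-slice ROI min-max SI range (left-closed
  bins, last bin closed).  A constant-intensity ROI degenerates to a
  single occupied bin.
* **Smoothing** by a 5-bin centered moving average, truncated (not
  padded) at the range ends so edge peaks survive.
* **Peak selection**: among all local maxima of the smoothed counts, the
  two of highest topographic prominence, the lower-SI one being the lean
  peak.  Equal-height summits are resolved by a leftmost-parent
  convention so that twin noise spikes inside one peak region cannot both
  claim full prominence.
* **Local minimum**: the argmin of the smoothed counts strictly between
  the two selected peaks; a plateau resolves to its midpoint, as does a
  plateau at a peak.
* **Ties at the threshold** count as fat (SI >= threshold).  On
  continuous-valued images ties have measure zero; the convention only
  matters for integer-valued toys.
* Slices whose smoothed histogram has fewer than two maxima, or fewer
  than two bins between the selected peaks, signal
  `noBimodalStructure`; segmentation proceeds only if an override covers
  the slice.  Empty-ROI slices yield empty mask slices and are logged.

Thresholds are **per slice**, never global, since coil shading and
composition shift the histogram from slice to slice.

## Volumetry and landmark geometry

All areas are cm^2, volumes ml, and the axial pitch is the **effective
slice thickness** `ST = (thickness + gap) / 10` cm -- 1.05 cm for the
10 mm / 0.5 mm acquisition this package mirrors.  Volume is pixel count x
pixel area x ST summed over the PF-D slice range; the tissue inside the
0.5 mm gap is unobserved, and multiplying by the effective thickness
interpolates across it.

Slices are indexed from 1 (most caudal) upward -- index arithmetic only
ever uses differences, so nothing depends on the base.  The axial height
of slice *k* relative to the L3-L4 intervertebral space is
`h_ref = (k - k_L3L4) * ST`, positive cranially; at ST = 1.05 cm the
slices one, three and seven positions above L3-L4 sit at 1.05, 3.15 and
7.35 cm.

Landmarks are inputs (or phantom metadata), never detected from images.
Five-slice windows are symmetric about the landmark slice except at the
femoral heads, where all five slices lie at or above the landmark.  Two
readings of "above" are possible; the default window `{L..L+4}` keeps
the single-slice member inside the five-slice set, and the strict
alternative `{L+1..L+5}` is available as `fhMode = "above"`.

## Scaling fits and prediction

For subjects with partial volume `p_i = A_i * ST` and measured total
volume `v_i`, the scaling factor is the least-squares slope through the
origin of `p` on `v`:

    f = sum(p_i v_i) / sum(v_i^2),

directly interpretable as the fraction of total VAT volume captured by
the landmark window (so five-slice factors are about five times
single-slice ones).  Prediction inverts it: `V = A * ST / f`.

Goodness of fit uses the **uncentered** R^2,
`1 - sum((p - f v)^2) / sum(p^2)`, the appropriate form for a model
without intercept.  A subtlety worth recording: at each orientation's own
least-squares slope the uncentered R^2 equals the squared uncentered
correlation `sum(pv)^2 / (sum(p^2) sum(v^2))` and is therefore identical
whether areas are regressed on volumes or vice versa.  Both columns are
reported for transparency, but they can only differ if a slope from one
orientation is reused in the other.  Gender-specific fits are the
default; pooled fits are available by passing `gender = NULL`.

## Agreement

Bland-Altman differences are `predicted - measured`, so positive bias
means overestimation.  The ranking statistic is the sample standard
deviation sigma of the differences (n - 1 denominator); limits of
agreement `bias +/- 1.96 sigma` are computed for plots but never used for
ranking.  `bestLandmark()` minimizes sigma, breaking exact ties toward
the more caudal landmark.

The sweep evaluates **in-sample** by default: f is fitted and sigma
measured on the same stratum, matching how such scaling factors are
usually reported.  `looMode = TRUE` switches to leave-one-out prediction
for an honest out-of-sample error; on 30-subject strata it inflates
sigma by roughly 5-15 %.

Age-tertile splits sort by age (ties by id) and cut into three groups
whose sizes differ by at most one.  With a remainder of one subject the
default convention gives it to the middle group (94 -> 31/32/31); the
alternative `"earliest"` convention (32/31/31) is a switch, since both
are defensible readings of "nearly equally sized".

## The synthetic generator

No patient images or tables ship with the package, so a two-level
generator provides inputs with exact ground truth.

**Phantoms** (image level) use a concentric-ellipse body: a subcutaneous
fat ring on the outside, an 8 mm abdominal wall, and a visceral cavity --
the ROI -- seeded with random elliptical fat blobs whose per-slice total
area follows a prescribed axial profile.  Fat pixels draw SI from the fat
peak distribution (default 0.8 +/- 0.05), lean pixels from the lean peak
(0.2 +/- 0.05), giving exactly the bimodal ROI histograms the
segmentation model assumes.  The ground-truth mask, its exact volume and
a landmark table are returned with the image.  The default in-plane grid
is 128 pixels at 3.3 mm (a ~42 cm field of view at reduced resolution);
the geometry is fully parameterized, and validation uses 64-128 pixel
grids, which keeps each phantom's generation and segmentation in the
sub-second range.  Phantoms with `|fat - lean| < 2 (sd_fat + sd_lean)`
carry a separability warning.  No MR physics is simulated: no echo-time
effects, water/fat swaps or bias fields -- intensity inhomogeneity beyond
global Gaussian noise is exactly what the per-slice histogram model is
robust to in real data, and passing phantom tests therefore says nothing
about that failure mode.

**Cohorts** (table level) draw one subject at a time from a gender
template: a skew-normal-shaped axial area profile parameterised by its
mode (`peakOffsetCm`, relative to L3-L4), spread, peak area and skewness.
The published distributions show only min/median/max bars per height, so
a unimodal skewed family is the minimal faithful shape.  Defaults were
frozen once, in this order:

1. **Peak offsets**: the study's largest female median areas span
   h_ref = -1.05 to 2.10 cm and the male ones 3.15 to 7.35 cm.  The
   female template peak sits at the caudal end of its band (-1.05 cm),
   the male at +4.2 cm.  Within the female band, more cranial placements
   blur the distinction between L3-L4 and L2-L3, because the fixed PF-D
   integration range penalizes landmarks caudal of the area peak (see
   "Why the landmark structure emerges" below).
2. **Skewness 1**: the profile must fall steeply into the pelvis (little
   VAT below the femoral heads) yet reach the diaphragm gradually; a mild
   positive skew encodes that asymmetry.
3. **Widths** (12.04 cm female, 14.18 cm male) solved analytically so the
   single-slice fraction at the optimum landmark matches the reported
   0.045 / 0.039.
4. **Amplitudes** (214 / 305 cm^2) solved so simulated mean totals match
   the reported 4.9 L / 8.1 L under the default between-subject jitter.
   Per-landmark mean areas are deliberately *not* calibrated -- no
   per-landmark reference values exist to calibrate against.

Between-subject variability (default CV 0.25) is decomposed: amplitude
carries the full CV (lognormal, mean-preserving -- overall fat amount
varies most, and cancels exactly in area/volume ratios), the peak offset
is jittered additively with SD = CV x template width (~3 cm of axial
body-shape variation), and the width varies least (0.3 CV).  Applying
one CV to all three parameters makes the sigma landscape nearly flat
across the lumbar landmarks -- width jitter is ratio-neutral about one
width away from the peak, rewarding distant landmarks -- which
contradicts the strongly landmark-dependent agreement the method shows
on real patients.  Observed areas add iid Gaussian noise (default SD
8 cm^2) per slice; negative draws truncate at zero and are counted.
Ages and BMIs are uniform on the study's ranges (18.6-70.7 years,
40.1-64.1 kg/m^2) and independent of volume, which deliberately mimics
the near-absence of BMI-volume correlation in this BMI range.

**Why the landmark structure emerges.**  A landmark's prediction error
is driven by the between-subject variance of the ratio area/volume.
Amplitude jitter cancels in the ratio; offset jitter contributes least
where the profile is flattest, i.e. at its peak; and because the total
is integrated over a fixed PF-D range, a caudal shift of the profile
also sheds mass over the pelvic boundary, a covariance that partially
stabilizes ratios at landmarks cranial of the mean peak and
destabilizes caudal ones.  With the female peak near L3-L4 and the male
peak 4 cm higher, the minimum-sigma landmark lands at L3-L4 for female
cohorts and at L2-L3/L1-L2 for male cohorts -- the same gender asymmetry
the method reports on patients, emerging from geometry rather than
being written into the code.

What passing these tests does **not** show: the generator has no
landmark mislocalisation, no subject-specific PF/D placement, no
correlated (non-iid) segmentation errors between adjacent slices, and no
heavy-tailed outliers; real agreement statistics will be worse than
synthetic ones in roughly the proportion these effects matter.

## Numerical choices and degenerate inputs

* Through-origin slopes use the closed form `sum(pv)/sum(v^2)`; a
  one-subject fit degenerates to `p/v`; all-zero volumes are an error.
* R^2 with `sum(p^2) = 0` is an error (undefined), as is Pearson
  correlation of a zero-variance vector.
* `sigma` requires at least two pairs.
* Sweep strata under three subjects are flagged and their statistics
  suppressed rather than reported.
* All generators take a mandatory seed, use it through an isolated RNG
  scope, and leave the caller's random state untouched; identical seeds
  give bit-identical output.

Validation problem sizes, chosen to exercise every code path while a
full test run stays in the tens of seconds: phantoms of 21-25 slices at
64-96 pixel grids, cohorts of the study's 94/36 stratum sizes, 50-seed
replications for the structural claims, and a 500-subject cohort for
parameter recovery against analytic expectations.

## Known limitations

* The ROI (abdominal cavity contour) is an input; the automatic
  boundary delineation plus manual editing used on real data is out of
  scope, so real-world use requires an external ROI source.
* Landmarks are inputs; no vertebra labeling.
* No intercept, robust or weighted regression variants; the scaling
  model is deliberately the plain through-origin fit.
* The reported scaling factors are dimensionless fractions and transfer
  across slice thicknesses, but they are calibrated to morbidly obese
  anatomy; applying them to leaner populations shifts the optimum
  landmark and the factors themselves.

## Session info

```{r}
sessionInfo()
```
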