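---
title: "Methods: Hounsfield units, gray-white matter ratios and pediatric normative modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hounsfield units, gray-white matter ratios and pediatric normative modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwrkit)
```

## Scope and model

`gwrkit` analyses regional attenuation on two axial head-CT slices of
children aged roughly 1 month to 18 years. The quantities of interest
are regional Hounsfield-unit (HU) means, the twelve gray-white matter
ratio (GWR) formulas in clinical use, the agreement between segmented-ROI
and circular-probe (DOT) sampling, and age-stratified normative
summaries. Slice selection and anatomical localization are done by a
human upstream; the package consumes a 2-D HU image with a co-registered
integer label map per slice and is agnostic to how the labels were drawn.

## Normative age-response curves

Regional mean HU is modelled as a function of age $x$ in months:

* power law $y = a\,x^{b}$ for gray-matter-dominated regions —
  whole-slice parenchyma (SL1: $a = 26.424$, $b = 0.025$; SL2:
  $25.5, 0.0233$), caudate nucleus ($28.394, 0.0211$) and cortical gray
  matter (SL1: $26.843, 0.0403$; SL2: $26.713, 0.039$);
* straight lines for the age-flat regions — putamen, thalamus and both
  white-matter compartments (slopes between $-0.0031$ and $0.0061$
  HU/month);
* a constant 15 HU for the ventricles, which show no age effect.

The age unit is months: evaluated at 200 months the parenchyma curve
gives ≈ 30 HU, the plateau value reported for older children, whereas a
year-based reading gives implausible values. Ages below 1 month are
clamped to 1 (the power laws diverge toward age zero and the youngest
normative subjects are about one month old). Lobar ROIs have no
published curve and are modelled as a 60/40 area-weighted GM/WM mixture
(`lobe_gm_weight`, configurable). The two SL1 white-matter probe sites
(frontal periventricular WM and posterior limb of the internal capsule)
share the generic WM-SL1 curve; no separate curves exist for them.

## The synthetic cohort generator

`sample_cohort()` draws a cohort of default size 42 (18 subjects under
24 months, 24 at or above — the stratification boundary used
throughout). Ages are drawn from truncated log-normal distributions
whose medians and IQRs match the reference cohort (young: median
≈ 5.5 months, IQR ≈ 3–10; old: median ≈ 91 months, IQR ≈ 48–148); the
right-skew toward infancy reflects how rarely older healthy children are
scanned. Each subject's per-region *true mean* is the curve value plus
an independent between-subject Gaussian deviation (default SD 1 HU).
The generic WM-SL1 truth is defined as the mean of its two probe-site
truths so that the measured value (mean of the two probe values)
round-trips exactly.

`render_phantom()` turns a subject's truths into a schematic phantom:
an elliptical brain outline (256×256 px, 0.5 mm isotropic by default), a
cortical ribbon along the outer 14 % of the ellipse radius, a lobar band
at 60–86 % radius split into angular sectors, and elliptical deep
structures over a parenchyma filler, all mirrored about the midline.
Voxel values are the region truth plus Gaussian voxel noise (default SD
3 HU). Two numerical choices matter:

* **Exact parenchyma round-trip.** The filler HU is solved per subject
  so that the area-weighted mean over the whole parenchyma mask (all
  tissue labels, ventricles excluded) equals the parenchyma truth.
  Hence with zero voxel noise *every* region's ROI mean equals its truth
  exactly, which the test suite asserts to floating-point tolerance.
* **Disjoint masks by construction.** Structures only claim filler
  pixels, so region masks never overlap and the parenchyma mask is a
  superset of all tissue submasks.

The phantoms are schematic by design: they reproduce the statistical
structure of the measurement problem (region topology, tissue contrast,
age trends, noise), not anatomy. Passing tests therefore validate the
measurement, ratio and statistics machinery — they say nothing about
localization accuracy on real scans, partial-volume effects at tissue
boundaries, beam hardening, or scanner/kVp differences, none of which
are modelled. One visible consequence: on real scans the ventricle DOT
reads systematically lower than the ventricle ROI (small probes avoid
the choroid plexus and margins), a bias the homogeneous phantoms cannot
reproduce; phantom ROI/DOT biases are near zero.

## Measurement

`roi_mean_hu()` is the arithmetic mean over all pixels carrying the
region's label, per side for bilateral regions, followed by
`bilateral_average()` (equal-weight mean of left and right, regardless
of area). `dot_mask()` uses the pixel-center-in-circle rule: a pixel
belongs to the dot iff its center lies within `diameter/2` (mm) of the
dot center — unambiguous, spacing-robust, no partial-volume weighting.
Coordinates are row-major pixel indices with the first pixel center at
(1, 1); fractional centers are allowed. The default dot diameter is
2.6 mm, the midpoint of the 2.4–2.8 mm protocol range. A dot whose mask
touches any pixel outside its target label raises a contamination error
rather than silently cropping: placement correctness is part of the
protocol. A dot so small relative to the spacing that it covers no pixel
center is likewise an error. HU values are carried as reals throughout;
no integer quantization.

Where a formula cites generic "WM-SL1", the value used is the mean of
the anterior and posterior probe values, since the protocol measures two
WM sites on SL1; single-subregion formulas use their named site.

## The GWR engine

Multi-region numerators and denominators are combined as the **mean** of
the cited regions: `(CN + PT)/WM-SL1` is `mean(CN, PT)/WM-SL1`. A
literal sum-over-single-region reading would put values near 2.5,
incompatible with the observed 1.2–1.4 range, and the source formulas
this catalogue adapts average their regions explicitly. `average2` is
the arithmetic mean of the `bg1` and `cortical` sub-ratios, computed per
subject; group medians of composites are medians of per-subject
composites. Bilateral averaging happens before ratio formation. Ratios
are scale-invariant (tested) and values below 1 are flagged with a
warning rather than rejected — a diseased brain is exactly the use case
in which they occur. GWR is computed from the DOT table by default (the
formulas' tissue compartments are probe-sampled); the engine accepts
either method's table and records provenance.

## Agreement

`bland_altman()` summarizes DOT − ROI differences by their mean (bias),
sample SD (n − 1 denominator) and limits of agreement at bias ±
1.96 SD; 1.96 is fixed, not a quantile parameter, and no confidence
intervals are attached to the limits. The sign convention (DOT minus
ROI) is fixed and tested: inflating all DOT values by +c shifts the bias
by exactly +c.

`icc_single_rater()` computes the single-measurement intraclass
correlation from two-way ANOVA mean squares. The form is a design
choice the protocol leaves open; the default is ICC(2,1) — two-way
random effects, absolute agreement — the conventional model for
intra-rater re-reads, with ICC(3,1) (consistency) available via `type`.
`simulate_rereads()` emulates re-reading a random 10 % of scans by
perturbing each stored measurement with independent Gaussian re-read
noise (default SD 0.5 HU); with zero re-read noise the ICC is exactly 1,
which pins down the perturbation model.

## Normative statistics

* **Quartiles**: linear interpolation between order statistics
  (`quantile` type 7, the spreadsheet default), fixed so IQRs are
  reproducible; verified against a sort-based oracle.
* **Normality gate**: Shapiro–Wilk at α = 0.05 per group; both groups
  must pass for the t-test branch, otherwise the two-sided Mann–Whitney
  U test. The t-test is Welch's (unequal variances), the safer default
  for an unpaired comparison.
* **Bonferroni families**: the report blocks have 14 segmented-ROI rows,
  9 probe rows and 12 GWR rows, and each block's row count is its
  default family size (configurable). Adjusted p-values are capped at 1.
* **Power-law fitting**: OLS of log y on log x, with R² reported on the
  log-log scale — the spreadsheet trendline convention the normative
  curves come from. A zero-variance response is defined to have slope 0
  and R² 0 with a warning. Age-response fits use ROI values for
  parenchyma and deep nuclei and DOT values for the GM/WM compartments,
  matching which method defines each compartment in the report tables.

## Noise calibration and parameter recovery

`calibrate_noise_for_r2()` inverts the log-log fit's variance
decomposition: for a power region with exponent $b$ sampled at ages $x$,
the log-scale signal SD is $|b|\,\mathrm{sd}(\log x)$, so additive HU
noise of SD $\sigma \approx \bar y \cdot |b|\,\mathrm{sd}(\log x)
\sqrt{(1-R^2)/R^2}$ yields the target $R^2$. At the reported $R^2$
values (0.38 parenchyma, 0.49 cortical GM) this gives ≈ 0.9–1.3 HU of
between-subject noise, consistent with the generator's 1 HU default.
`recover_power_exponent()` uses this to run the package's
parameter-recovery study: 20 seeded cohorts of 500 subjects with ages
uniform on [1, 216] months, each fit by `fit_power_curve()`; the mean
recovered exponent lands within ±0.005 of the generating value
(standard error ≈ 0.0003). Note that on the default *cohort* age
distribution — strongly right-skewed rather than uniform —
$\mathrm{sd}(\log x)$ is larger, so cohort-level R² values run higher
than the uniform-age calibration targets; this is a property of the age
design, not of the noise model.

## Problem sizes and determinism

The test suite uses one 42-subject fixture cohort, a 14-subject noisy
measured cohort, 160-pixel phantoms for pipeline I/O tests, 64-pixel
coarse phantoms for brute-force oracles, and 100 seeded replicates for
the direction properties (young-stratum medians below old for
parenchyma, caudate, cortical GM and cortical GWR). All randomness flows
from explicit integer seeds; per-subject voxel-noise seeds are derived
deterministically from the cohort seed, and a run's seed is recorded in
every output manifest.

## Known limitations

* Phantom geometry is schematic; no anatomy, no 3-D volumes, no
  partial-volume or beam-hardening physics.
* The fully automated whole-brain GM/WM segmentation ratio ("GWR auto")
  is out of scope, as are outcome-prediction thresholds.
* Exact per-subject ages of the reference cohort are unknown; the
  generator matches stratum medians and IQRs, not individual ages.
* The measurement-noise magnitude of real HU reads is not published;
  the calibration against reported R² values is this package's own
  construction.
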