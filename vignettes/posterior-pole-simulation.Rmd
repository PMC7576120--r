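---
title: "Simulating and analysing the posterior pole in situs inversus of the optic disc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the posterior pole in situs inversus of the optic disc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siodscan)
```

## The scientific question

Situs inversus of the optic disc (SIOD) is a rare congenital anomaly in which
the retinal vessels emerge from the disc nasally before arching back
temporally. SIOD eyes also show a characteristic circumpapillary retinal
nerve fiber layer (RNFL) profile: the two thickness humps formed by the
superior and inferior axon bundles sit closer to the nasal side than in
normal eyes ("nasal crowding").

One candidate explanation is purely geometric. If the optic disc — anchored
by the Bruch's membrane opening (BMO) — sits *closer to the fovea* than it
would normally, while the axonal architecture of the surrounding retina is
otherwise unremarkable, then a measurement circle centered on the BMO is
effectively displaced *temporally* relative to the architecture that the
axon bundles follow. Seen from that displaced center, both humps appear
rotated toward the nasal side. The prediction is sharp: move the scan circle
back nasally along the fovea–BMO axis by the group mean distance deficit and
the profile should normalize.

`siodscan` implements this whole argument as a reproducible in-silico study:
a synthetic posterior-pole generator, per-eye geometry measurements,
circle-scan extraction with post-hoc repositioning, and clustered
case-control statistics.

## The synthetic thickness field

No public OCT data exist for this condition, so the package generates
scenes. The noiseless RNFL field of one eye is defined in polar coordinates
$(r, \theta)$ about the **architectural disc center** $c_a$ (the point the
axon field converges on):

$$T(r, \theta) = \frac{r_0}{r}\left[\,b + A_s\, g(\theta; +\theta_h, \sigma)
  + A_i\, g(\theta; -\theta_h, \sigma)\,\right]$$

where $g$ is a wrapped Gaussian on the circle, $\theta$ is measured from the
eye's temporal direction (the fovea–disc axis), and $b$ absorbs a shared
per-subject offset. This is the simplest field with the two properties the
analysis needs:

* **Double hump anchored to the fovea–disc axis.** The humps sit at
  $\pm\theta_h$ from the temporal horizontal of each eye's own axis, which
  is what makes "nasal" and "temporal" meaningful across eyes.
* **Axon conservation.** The $1/r$ radial decay makes
  $\oint T \, r\,d\phi$ independent of radius: the same axons cross every
  enclosing circle. `circle_flux()` verifies this numerically to well below
  0.5%.

A SIOD eye is the *same* field with one change: the measured BMO center is
displaced from $c_a$ toward the fovea by `displacement` micrometers, along
the fovea–$c_a$ line. Control eyes have zero displacement, so for them the
BMO center and the architectural center coincide. This one-parameter lesion
is the package's encoding of the hypothesis "the disc is too close to the
fovea, the architecture is preserved".

The disc interior (the BMO ellipse) is masked to a sentinel thickness of 0
rather than extrapolated; the default scan radius of 1.73 mm keeps every
profile sample well clear of the mask for default BMO sizes.

## Generator parameters

| parameter | default | units | why |
|---|---|---|---|
| arch distance mean | 4680 | um | normative fovea-to-disc-center distance |
| arch distance SD (between / within subject) | 200 / 165 | um | total eye-level SD ~260 um, with paired eyes correlated |
| displacement mean | 465 | um | the SIOD distance deficit under study |
| displacement SD | 120 | um | see below |
| axis angle mean / SD | -7.5 / 3.3 | deg | disc slightly superior; group-independent |
| baseline $b$ | 50 | um | temporal floor of the profile |
| hump amplitudes $A_s, A_i$ | 80 | um | profiles span ~50-130 um |
| hump angle $\theta_h$ / width $\sigma$ | 75 / 25 | deg | normal double-hump anatomy |
| reference radius $r_0$ | 1.73 | mm | the standard 3.46 mm scan circle |
| BMO semiaxes | (0.88, 0.85) | mm | ellipse area ~2.35 mm^2 |
| pixel noise SD | 4 | um | raster measurement noise |
| subject effect SD | 6 | um | shared thickness offset of paired eyes |
| arcade half-spread | 2.711 (SD 0.577) | mm | inter-arcade distance ~1807 units at 333.3 units/mm |
| age | N(58, 14), truncated 25-90 | years | clinic-plausible cohort |
| axial length | N(24.25, 0.3) | mm | emmetropic-to-mildly-myopic range |

The displacement SD is not an observable with a published value; 120 um was
chosen once so that (a) truncation at zero is negligible (the mean sits
almost 4 SDs above zero, so the realized mean displacement is 465 um to a
small fraction of a micrometer), and (b) the SIOD distance SD
($\sqrt{260^2 + 120^2} \approx 286$ um) stays below the control-vs-SIOD
separation. The axis angle is drawn from one distribution for both groups:
the reported group difference in that angle is not statistically
established, so the generator deliberately does not encode it.

The generator works in a canonical right-eye frame (origin at the fovea,
+x nasal, +y superior). Left eyes are produced from the identical random
draws and then mirrored about the vertical axis, so a left eye and the
right eye of the same seed are exact mirror images; `canonical_scene()`
undoes the mirroring before measurement.

## What the generator does not emulate

Passing tests on this generator show that the *analysis chain* is correct
and that the repositioning logic does what the geometric argument predicts.
They do not show that real SIOD eyes satisfy the model. In particular the
generator has no B-scan physics (speckle, shadowing), no segmentation
error, no vascular contribution to measured RNFL thickness, no true
fundus-photograph processing (arcades are parametric parabolas through the
architectural center), and no refractive magnification effects. The
displacement lesion is exactly collinear with the fovea-disc axis by
construction; in real eyes the deficit need not be.

## The measurement and scan stages

`measure_eye()` produces the per-eye geometry: the foveo-BMO-center
distance (Euclidean, in um), the margin distance (nearer intersection of
the fovea-to-center ray with the BMO ellipse — the along-axis reading of
the temporal margin), the signed axis angle (negated so a superior disc
gives a negative angle, matching the reporting convention in this
literature), the BMO ellipse area, and the vertical inter-arcade distance
at the fovea, kept deliberately in the arcade curves' native photograph
units.

`resample_circle()` bilinearly interpolates a rendered raster along a
circle of radius 1.73 mm, 720 samples at 0.5 degree spacing. Profile angle
0 is temporal and angles follow the temporal-superior-nasal-inferior
ordering; the `axis_deg` argument rotates the angular origin onto the
per-eye foveo-BMO axis, which is how fovea-to-disc-aligned acquisition
works and what makes hump positions comparable across eyes. On mirrored
(left-eye) rasters the direction vectors are mirrored, so extracted
profiles already carry per-eye temporal/nasal semantics for both
lateralities.

`clock_hour_summary()` averages 60 consecutive samples per 30-degree
sector. The mapping is fixed as hour 9 = temporal (0 deg), hour 12 =
superior (90 deg), hour 3 = nasal (180 deg), hour 6 = inferior (270 deg);
sector $h$ is centered at $((h-9)\cdot 30) \bmod 360$ degrees and covers
$\pm 15$ degrees with a half-open $[c-15, c+15)$ grid rule so every sample
belongs to exactly one sector. `peak_locations()` smooths with a 15-degree
circular moving average before taking the superior (0-180) and inferior
(180-360) argmax; exact ties break toward the temporal side; flat profiles
are flagged degenerate rather than given arbitrary peaks.

`reposition_center()` implements the central manipulation: move the circle
center by a given number of micrometers along the unit vector from the
fovea through the BMO center (positive = nasal). Because a SIOD scene's BMO
center sits exactly `displacement` um short of the architectural center on
that same line, repositioning by the true displacement recovers the
architectural center *exactly* — this is the normalization theorem the
property tests exercise, and the reason the pipeline's estimated group
difference $\hat\Delta$ normalizes profiles up to its own sampling error.
Applied to a control eye, the same nasal shift over-shoots the architecture
and crowds the humps *temporally* — the myopia-like reverse manipulation,
which the tests assert as well.

## Statistics

Eyes are not independent: SIOD subjects may contribute two eyes, and the
repositioned condition reuses the same eyes. All group comparisons
therefore use a cluster-robust mean model: identity link, independence
working structure, and sandwich standard errors with clusters = subjects.
For a two-group mean this reduces to closed form — the difference of group
means with variance $\sum_c (\sum_{i \in c} e_i)^2 / N^2$ summed within
each group — which is implemented directly and cross-checked in the tests
against an independent sandwich-estimator implementation. Wald tests use
the normal reference distribution, the convention for estimating-equation
fits; no small-sample correction is applied by default (a `small_sample`
flag enables a $G/(G-1)$ factor). When a contrast has exactly zero
estimate and zero standard error (degenerate all-identical fixtures) the
p-value is defined as 1; a nonzero estimate with zero standard error gives
p = 0.

Controls are matched greedily: cases in eye-id order, each taking its $k=2$
nearest eligible unused pool eyes by standardized (age, axial length)
distance, with eligibility windows of 10 years and 0.5 mm and seeded
random tie-breaking, making the result invariant to input row order. The
matcher works per case *eye* (two controls per eye, not per subject).

The 12 clock-hour sectors are compared across the three conditions
(control, SIOD, repositioned SIOD) per hour, with the three pairwise
contrasts flagged at the Bonferroni threshold $0.05/12 \approx 0.0042$.

## The pipeline

```{r, eval = FALSE}
cfg <- experiment_config(seed = 1)
rep <- run_experiment(cfg)
print(rep)
write_experiment_report(rep, "results")
```

`run_experiment()` chains every stage: generate (15 SIOD subjects,
bilateral with probability 7/15, a control pool of 150 subjects), match
2:1, measure, compare the five geometry measures, set
$\hat\Delta = \bar d_{\text{control}} - \bar d_{\text{SIOD}}$ from the
foveo-BMO-center distance (a config flag switches to the margin distance),
reposition every SIOD circle by $\hat\Delta$ along its own axis (a flag
adds the control-eye reverse check, and another switches to a group-mean
axis), and run the sector comparison. Everything — including the per-eye
raster noise — derives deterministically from the single config seed, and
re-running a config byte-reproduces every output file.

Because $\hat\Delta$ is estimated from ~22 case eyes its sampling error
(roughly 75 um SE under defaults) is shared by *all* repositioned eyes, so
individual seeds can show residual repositioned-vs-control differences in
the vertical sectors; this is a property of the fixed-shift design itself,
not of the implementation, and disappears as the cohort grows.

## Numerical choices and problem sizes

Bilinear interpolation against the closed-form field agrees to better than
0.02 um at the default 200 x 200 raster (the acceptance bound is 1 um);
the 16-bit TIFF serialization quantizes thickness at 0.1 um. Simulation
sizes used by the test suite were chosen to keep the full suite around two
minutes on one CPU while leaving Monte-Carlo error well below the margins
being asserted: 200 replicate cohorts for displacement recovery, 200
replicate null cohorts (at a 100 x 100 raster, where interpolation error
is still two orders of magnitude below the pixel noise) for the sector
type-I check, and 1000 eyes for the generator calibration round-trip.

## Limitations

The generator is a geometric idealization: a single displacement parameter,
perfectly collinear landmarks, rotationally clean humps. The cluster-robust
z-tests are mildly anti-conservative at extreme tails with ~60 clusters.
The inter-arcade measurement shares no scale with the OCT distances by
design (native photograph units), so it can only support "no group
difference" conclusions, not effect sizes. And the 2:1 matcher is greedy,
not optimal; with generously sized pools this is immaterial, but tight
pools can fail where an optimal matching would succeed — the failure is
explicit, naming the unmatched case.
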