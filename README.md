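# siodscan

Posterior-pole geometry and circumpapillary RNFL profile analysis for situs
inversus of the optic disc (SIOD), as a reproducible in-silico study.

## The problem

SIOD eyes show "nasal crowding": the two humps of the circumpapillary
retinal nerve fiber layer (RNFL) thickness profile — the superior and
inferior axon bundles — sit abnormally close to the nasal side. A geometric
hypothesis explains this without any abnormality of the axons themselves:
the optic disc (anchored by the Bruch's membrane opening, BMO) simply sits
closer to the fovea than normal. A scan circle centered on that displaced
BMO is then temporally off-center with respect to the axonal architecture,
which rotates both apparent hump positions nasally. The testable
consequence: reposition the scan circle nasally along the fovea–BMO axis by
the group mean distance deficit, and the SIOD profile should normalize.

`siodscan` builds the full analysis for this argument around a synthetic
posterior-pole generator (no clinical OCT data are public for this
condition):

* **Synthetic scenes** — an axon-conserving RNFL field
  `T(r, θ) = (r0/r)·[b + A_s·g(θ−θ_h) + A_i·g(θ+θ_h)]` (wrapped-Gaussian
  double hump anchored to the per-eye fovea–disc axis) with landmark
  geometry, paired-eye correlation, and SIOD as a single displacement
  parameter: the BMO center moved toward the fovea (465 μm on average)
  within otherwise normal architecture. Rasters render to 200×200 thickness
  maps over a 6×6 mm field (16-bit TIFF + JSON sidecar).
* **Geometry** — per-eye foveo-BMO-center and margin distances, signed axis
  angle, BMO area, vertical inter-arcade distance.
* **Circle scan** — bilinear resampling of the 3.46 mm circle at arbitrary
  centers, scan-center repositioning along the foveo-BMO axis, clock-hour
  sectors, double-hump peak localization.
* **Cohort statistics** — 2:1 age/axial-length matching, cluster-robust
  (GEE-style sandwich) group means for paired eyes, chi-square contingency
  test, Bonferroni-corrected 12-sector comparisons.
* **Pipeline** — one call (or one CLI command) from config seed to report.

## Worked example

```r
library(siodscan)

## one SIOD eye at the canonical study geometry
s <- generate_scene(group = "siod", rng_seed = 1,
                    arch_distance = 4680, displacement = 465)
measure_eye(s)$foveo_bmo_center_distance
#> [1] 4215

## the full in-silico experiment
cfg <- experiment_config(seed = 1)
rep <- run_experiment(cfg)
print(rep)
#> <experiment_report>
#>   eyes: 22 siod / 44 control; subjects: 15 / 44
#>   estimated shift (control - siod center distance): 430.5 um (applied 430.5 um)
#>   flagged sectors at p < 0.0042: control vs siod 12/12, control vs repositioned 0/12
rep$comparisons$foveo_bmo_center_distance
#> foveo_bmo_center_distance: control 4671.93 +/- 33.66 vs siod 4241.47 +/- 82.92;
#>   diff 430.46 (SE 89.49), p = 0.0000
```

For this seed the generated cohort happens to match the study arithmetic
exactly (22 SIOD eyes from 15 subjects, 44 matched control eyes). The
estimated shift of 430.5 μm is the cluster-robust control-minus-SIOD mean
foveo-BMO-center distance difference — one sampling realization around the
generator's true 465 μm displacement. Before repositioning, every sector
differs between groups (SIOD thicker in nasal hours 1–5, thinner in
temporal hours 7–11); after repositioning each SIOD circle nasally by the
estimated shift along its own foveo-BMO axis, no sector remains flagged:

```r
round(rep$sector_table[c(1, 3, 7, 11), c("hour", "mean_control", "mean_siod",
                                         "mean_repositioned",
                                         "p_control_vs_siod",
                                         "p_control_vs_repositioned")], 4)
#>    hour mean_control mean_siod mean_repositioned p_control_vs_siod p_control_vs_repositioned
#> 1     1      68.1593   96.2561           67.8092             0e+00                    0.8653
#> 3     3      49.8393   65.6967           49.3644             0e+00                    0.7939
#> 7     7     114.6070   84.9566          113.6937             0e+00                    0.6871
#> 11   11    113.9583   84.3692          113.2136             0e+00                    0.7480
```

`write_experiment_report(rep, "results")` serializes the measurement,
match, sector and mean-profile tables (CSV) and a JSON summary. The same
pipeline is scriptable via `inst/cli/siodscan.R` with subcommands
`simulate`, `measure`, `scan`, `reposition`, `analyze`, `run-all`.

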