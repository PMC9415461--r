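---
title: "Phenotypic mode-of-action profiling by Fourier feature reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic mode-of-action profiling by Fourier feature reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofft)
```

## The problem and the model

Continuous label-free imaging (quantitative phase / holotomographic
microscopy) of drug-treated cells yields, for every cell in a field and
every imaging cycle, a panel of eleven phenotypic parameters: seven
morphology measures (cell area in um^2 and as a percentage of the field,
perimeter, form factor, extent, compactness, eccentricity) and four
composition measures derived from the refractive index (mean RI, average
dry mass density, dry mass, granularity). Compounds with a shared mode of
action — for instance microtubule disruptors such as colchicine and
vinblastine versus the stabilizer paclitaxel — leave recognizably similar
traces in these time series, but comparing dozens of 400-point curves by
eye does not scale.

The pipeline implemented here reduces each condition to a 22-number
signature and clusters conditions on it:

1. **Aggregate.** Per condition, average each parameter over all cells
   present at each cycle (population mean and sample SD, $n-1$
   denominator).
2. **Center and scale.** Z-score each parameter's mean series over its
   cycles. Centering annihilates the DC term of the transform; scaling
   makes amplitudes comparable across parameters with different units.
3. **Transform.** Apply the discrete Fourier transform
   $X_k = \sum_{n=0}^{N-1} x_n e^{-i 2 \pi k n / N}$
   and keep, per parameter, only the dominant positive-frequency bin: its
   index $k^\*$, amplitude $2 |X_{k^\*}| / N$, and phase
   $\arg X_{k^\*}$. A monotone drift lands in $k^\* = 1$; the amplitude
   measures how wave-like the excursion is, and the phase encodes which
   part of the wave the acquisition captured (rising, falling, peaked).
4. **Assemble and normalize.** Stack the 11 amplitudes and 11 phases into
   a conditions x 22 matrix and z-score each column across conditions.
5. **Cluster.** Pearson-correlate condition rows and run agglomerative
   clustering on the distance $d = 1 - r$ (average linkage by default).

Conditions sharing a mode of action end up in the same flat cluster; a
stabilizer-like condition anti-correlates with disruptor-like ones.

## What the synthetic-data generator emulates

No public per-cell dataset accompanies the study system this package
models, so the generator is a first-class module rather than a test
convenience. It emulates a 236 um x 236 um field imaged every 3 min for
20 h (400 cycles) seeded with 15-25 cells, and three archetypal
conditions:

* **control** — slow growth in area and dry mass, stable shape, division
  at 0.03 per cell per hour;
* **stabilizer** — mitotic arrest from 10 h with rounding (form factor
  up, eccentricity down), dry mass density falling through the first half
  of the acquisition at near-constant dry mass;
* **disruptor** — area contraction of more than 20% within ~2 h, dry
  mass density rising along the acquisition with a slight fall at the
  end, reduced division, and a late death hazard (necrosis) that
  truncates tracks from ~12 h.

Population dynamics are piecewise-linear mean trajectories with knots at
the behaviorally meaningful times (2 h, 10 h, end of run). The knot
amplitudes were placed once, inside the reference per-parameter axis
ranges (e.g. dry mass 80-250 pg, mean RI 1.34-1.37), with enough margin
that population means stay inside those ranges across seeds. Two
parameters are derived to keep per-record identities exact: relative area
(`100 * area / field_side^2`) and compactness (`1 / form_factor`); mean
RI is tied to dry mass density through the specific refractive increment
(`mean_ri = n_m + alpha * dmd`), and cell volume is carried internally as
`dry_mass / dmd` so that mass conservation holds to machine precision.

Heterogeneity has two layers, chosen to make SD bands visibly nonzero
without drowning the trends: a lognormal per-cell multiplicative effect
(log-SD 0.1, one draw per cell per parameter, constant in time) and
stationary AR(1) measurement noise (autocorrelation 0.6, per-parameter
SDs of roughly 1-2% of each parameter's working range). Values are
clipped to physical domains only (positivity; eccentricity, extent and
form factor in [0, 1]), never to the calibration ranges — the ranges are
an emergent property of the trajectory design, which the test suite
checks rather than enforces.

What the generator does **not** emulate: cell-cell contact and crowding,
segmentation/tracking errors, focus drift, synchronized-population
effects, and multimodal responses within one condition (e.g. the mix of
arrested and cytokinesis-failed cells a stabilizer really produces).
Passing tests therefore demonstrate that the analysis recovers groupings
when condition differences are of the designed kind and magnitude — not
that the pipeline is robust to every artifact of real acquisitions.

## The synthetic image pathway

`simulate_field_frames()` renders each simulated cell as a fixed-position
ellipse whose area and eccentricity follow its trajectory, with a
semi-ellipsoidal height dome scaled to the target volume and a uniform RI
excess `alpha * dmd` modulated by multiplicative white-noise texture (the
granularity carrier, relative SD 0.45, bounded so RI never drops below
the medium). The morphometry module then re-measures the eleven
parameters from the rendered masks and maps. Area, dry mass, volume, RI
and eccentricity round-trip within 5% (mostly rasterization and texture
averaging); perimeter-driven parameters (perimeter, form factor,
compactness, extent) reflect the smooth rendered ellipse, not the
trajectory targets, because an ellipse cannot carry an irregular-boundary
form factor of 0.4. The image pathway exists to exercise the morphometry
definitions end to end, not to reproduce the trajectory statistics.

Frames for a full default acquisition (472 x 472 px x 400 cycles x 3
maps) occupy gigabytes; examples and tests therefore render smaller
fields and shorter runs, which exercise identical code paths.

## Morphometry definitions and numerical choices

The eleven parameters are recomputed with standard definitions: area from
pixel count; perimeter as the polygon length of the marching-squares
contour at the 0.5 level of a 3x3 box-smoothed binary mask (smoothing
removes the staircase bias, which is +6-9% for a raw digitized disk,
bringing the estimator within 1% on disks and ellipses); form factor
`4*pi*A/P^2` and compactness its exact reciprocal; extent against the
axis-aligned bounding box; eccentricity from the second-moment equivalent
ellipse of the pixel coordinates (population covariance, no pixel-width
correction — the test oracle uses the same convention); dry mass as
`sum((ri - n_m) * height) * px^2 / alpha` with the specific refractive
increment `alpha = 0.19` um^3/pg (mid-range of the accepted 0.18-0.21 for
cellular dry matter); volume from the height map; dry mass density their
ratio; granularity as `10 + 100 * sd` of the high-pass RI inside the
cell, using a mask-normalized local-mean window of 2 um — an affine map
placing typical textures in the 5-15 display range. Labels under 5 pixels
are skipped with a warning as sub-resolution objects.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `interval`, `duration` | 3, 20 | min, h | give the canonical 400 cycles |
| `field_side` | 236 | um | canonical field geometry |
| `initial_cells_min/max` | 15, 25 | cells | canonical seeding range |
| `cell_effect_sd` | 0.1 | log-units | visible but not dominant cell heterogeneity |
| `noise_autocorr` | 0.6 | — | imaging noise is serially correlated at 3-min spacing |
| `ri_increment` | 0.19 | um^3/pg | standard dry-mass refractive increment |
| `medium_index` | 1.333 | — | aqueous medium |
| `pixel_size` | 0.5 | um/px | desk-scale rendering (472 px across the field) |
| linkage | average | — | standard for correlation heat-map dendrograms; single/complete exposed |

## Degenerate inputs and tie-breaks

Constant series are rejected at `center_scale` (zero variance carries no
frequency information) rather than silently producing a zero spectrum.
The dominant-bin search runs over `k = 1 .. floor(N/2)`, excluding DC
(meaningless after centering) and, for even `N`, the Nyquist bin (its
amplitude is not representable as a single tone's); near-equal amplitudes
(within 1e-9 relative, covering FFT round-off) resolve to the smallest
frequency. Empty cycles after total cell loss are filled by last
observation carried forward and flagged, so the transform always sees a
full-length vector. The feature-matrix normalization refuses fewer than
three conditions (a z-score across two points is just a sign).

## Design choices where the design was open

* **Per-condition centering.** Each condition's series is centered and
  scaled independently; pooling conditions before scaling would let a
  large-amplitude condition set the scale for all others.
* **Normalization of the worked-example table.** The packaged
  four-condition feature table ships in a pre-normalized form,
  but its columns are not unit-variance under any single obvious scaling,
  so the package treats it as un-normalized input and applies its own
  column z-scoring before correlation. This reproduces both the reference
  grouping ({control, stabilizer} vs the two disruptors) and the
  expected negative stabilizer-disruptor correlations; correlating the
  printed values directly reproduces only the grouping.
* **Amplitude scaling `2|X_k|/N`.** Any fixed scaling cancels after
  column z-scoring; this one makes a unit cosine report amplitude 1,
  which keeps unnormalized exports interpretable.
* **Signed phases.** Phases are kept signed in `(-pi, pi]` through
  normalization and clustering; absolute values are a display convention.
* **Amplitude and phase blocks normalized separately** (each column on
  its own), since they live on incommensurate scales.
* **Sample SD (n-1)** for all aggregation and z-scoring.
* **Replicates are explicit.** Each simulated replicate is its own
  condition row; downstream stages accept any replicate structure, and
  the recovery report scores flat clusters against known archetype labels
  with the adjusted Rand index.

## Problem sizes used by the checks

The bundled checks simulate the full default acquisition (400 cycles,
15-25 cells) for calibration and end-to-end recovery: 3 archetypes x 20
seeds for the range calibration, 3 archetypes x 3 replicate seeds for
recovery, and 100 fields for the seeding-range check. Image-pathway
checks use 40-120 um fields over 2-10 cycles, where rasterization
tolerances are already informative.

## Known limitations

* The archetype trajectories are a stylized reading of qualitative
  phenotype descriptions; amplitudes between the knots are this package's
  calibration, not measured biology.
* One dominant Fourier bin per parameter discards multi-phasic structure;
  two conditions differing only in a secondary oscillation are
  indistinguishable in the feature space.
* Per-cell spectra (screening outliers within a condition) are not
  implemented; the transform sees only population means.
* Granularity is an operational texture definition; instrument-specific
  granularity measures may scale differently.
* The dendrogram carries no significance measure; with four conditions a
  two-block partition is descriptive, not inferential.
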