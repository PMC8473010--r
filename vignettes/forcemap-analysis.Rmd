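---
title: "Breakthrough detection and phase mapping of AFM force-volume data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakthrough detection and phase mapping of AFM force-volume data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcemapr)
```

## The measurement and the model

In a force-volume (force-mapping) experiment an AFM tip records one
force-distance approach curve per cell of a rectangular grid over a
supported lipid bilayer — typically a 16 × 16 grid over a 5 × 5 µm field,
so 256 curves spaced 0.3125 µm apart. As the tip indents the membrane the
force rises until, at the *breakthrough (piercing) force*, the tip
ruptures the bilayer and jumps into contact with the solid support. The
rupture appears as a discontinuity in the curve, and the z-extent of that
discontinuity measures the bilayer thickness at that spot. Collecting the
per-cell breakthrough force and thickness gives co-registered mechanical
and topographic maps, which in phase-separated membranes resolve the
stiffer, thicker liquid-ordered (Lo) domains from the liquid-disordered
(Ld) background.

`forcemapr` automates this per-curve analysis and the downstream mapping,
clustering and morphometry.

## Kink detection by coordinate rotation

Both ends of the rupture discontinuity are *kinks*: points of locally
high curvature. The rupture onset is a "shoulder" where the slope of F
drops (often without F itself decreasing), and the rupture completion is
the opposite shoulder where the tip meets the hard support. Neither needs
to be a local maximum of the raw curve, so plain peak picking misses
them. The detector therefore rotates the curve in the force-distance
plane by a small set of angles (0, 4.5, 9, 13.5, 18 degrees by default)
and runs a local-maximum detector ([peakdet()], the classic
Billauer scan) on the rotated force coordinate at each angle; a kink
whose slope change straddles `tan(angle)` becomes a genuine local maximum
at that angle. Detections from all angles are pooled into a union set.

Three numerical conventions matter here:

* **Coordinate frame.** The rotation acts on rows `[F, t]` where
  `t = max(z) - z` is the distance advanced toward the support, so the
  stated positive angles tilt descending shoulders into maxima. Kinks of
  the opposite curvature class (rupture completion, tip-membrane contact)
  are found by running the same detector on the negated rotated
  coordinate, which is exactly the detection on −F(z).
* **Units as scale.** Rotation mixes force and distance, which is only
  meaningful on a fixed common scale. The package standardizes every
  curve to nN/nm at load time (SI exports are converted automatically)
  and rotates those raw values. This keeps the geometry of the problem:
  a 2–9 nm z-jump projects to a 0.15–0.7 nN drop at 4.5–18°, far above
  realistic force noise. Min–max rescaling of each curve would instead
  compress the few-nm rupture region by the full 400 nm z-travel and push
  its rotated prominence below the noise floor, so it is deliberately not
  used.
* **Prominence and merging.** `delta` (default 0.1 nN) is the peakdet
  prominence: it must exceed the peak-to-peak force noise (about 5 SD for
  the 0.02 nN noise typical of processed curves) and stay below the
  smallest rotated rupture drop, `thickness_min * sin(4.5°) ≈ 0.12 nN`.
  The same physical kink detected at several angles is merged when two
  detections lie within `merge_threshold` (default 2.0 in the Euclidean
  nN/nm metric, absorbing the ~1 nm jitter of noisy detections across
  angles); merging is transitive and keeps the smallest-angle detection,
  which is the least displaced one. Detections at the first or last
  sample are discarded — a kink needs neighbours on both sides.

Each surviving descending kink is paired with its nearest subsequent
ascending kink along the approach; the pair's z-distance is the local
membrane thickness and the force at the start kink is the breakthrough
force. Pairings are decided independently per kink rather than by greedy
consumption, so a spurious noise detection on the long zero-force
baseline cannot steal the true partner of the rupture onset.

## Event filtering, ranking and maps

Kink pairs are plausibility-filtered with closed bounds: force at least
0.5 nN, thickness between 1.5 and 9 nm (all configurable). If several
events survive in one curve, the one farthest from the support is
*primary* and the rest are *secondary* (closer to the mica); beyond two,
extras are flagged. Maps are assembled one value per cell from the chosen
channel and rank; cells with no surviving event stay flagged `missing`
and render black, cells with several same-rank events take the first and
are flagged `multiple`. Missingness is a flag, never a sentinel value, so
map statistics are uncontaminated.

## Phase clustering

Per-curve primary (force, thickness) points are clustered into two groups
with k-means (10 restarts, fixed seed, deterministic). Features are
z-score standardized because nN and nm are incommensurate; a
thickness-only mode is available for comparison with thickness-histogram
clustering. The lower-mean-force cluster is Ld, the higher Lo. The
summary reports per-phase point fractions, thickness mean ± sample SD,
the *max mismatch* (largest Lo thickness minus the mean Ld thickness) and
the *average mismatch* (difference of phase thickness means), the latter
being the number comparable to a height mismatch read off AFM images.

## Domain morphometry

Height images (or intensity masks) are thresholded (Otsu by default;
polarity is a flag because height images are bright-Lo while dye-exclusion
images are dark-Lo), labelled with 8-connectivity, and size-filtered
(`min_area` 4 px). Per domain the table records area (pixel count ×
pixel area), perimeter and circularity `4πA/P²`. The perimeter uses a
four-direction Crofton (intercept-count) estimator: a raw boundary-pixel
count overestimates P by up to ~27% and systematically deflates
circularity, while the Crofton estimate is exact in expectation for
isotropic boundaries (a rasterized disc of radius 50 px measures within
[0.95, 1.0] after the ≤1 clip; raw values slightly above 1 from
discretization are clipped and flagged). Height mismatch is the mean Lo
height minus mean Ld height, with an SD across domains when there are at
least two.

## What the generators emulate — and what they do not

`simulate_force_curve()` renders the approach as baseline → linear
indentation ramp → rupture discontinuity → hard-support ramp clamped at a
setpoint, plus Gaussian force noise. The discontinuity is a z-jump at
constant force spanning exactly `thickness`, because the thickness is
defined as the z-length of the discontinuity; this makes the generator
truth directly comparable to the paired-kink output. Defaults: 400 nm
travel at 0.2 nm sampling, contact at 30 nm, stiffness 0.2 nN/nm, rupture
at 2 nN over 4 nm, noise SD 0.02 nN. With these defaults the rupture
onset and completion fall exactly on sample positions, so noiseless
curves are recovered with zero quantization error; under noise, the
recovered force and thickness are unbiased to within 0.02 nN / 0.2 nm,
and roughly 2–6% of curves lose their event to a large noise excursion at
the onset (those cells become the black dots of the map — real force maps
show the same).

`simulate_force_grid()` draws per-cell (force, thickness) from per-phase
normal distributions — defaults Lo 6 ± 0.3 nN / 3.0 ± 0.2 nm, Ld
3 ± 0.3 nN / 2.2 ± 0.2 nm, i.e. a clearly separated force contrast with a
sub-nm thickness mismatch — over circular Lo domains (cell phase by
centre-in-disc membership), then synthesizes a full curve per cell with
the indentation stiffness scaled so the ramp spans 10 nm at any drawn
force. `simulate_domain_image()` rasterizes discs and ellipses with an
analytic truth table (Ramanujan's approximation is the ellipse-perimeter
oracle).

The generators target detector validation, not contact mechanics: no
Hertzian indentation curvature, no adhesion on retract, no tilt or drift
in the baseline, no correlated (1/f) noise, and domain boundaries are
ideal circles. Passing tests therefore demonstrate correctness of the
detection/mapping machinery under controlled conditions, not performance
on every instrument artefact; the thresholds and `delta` remain the
user's handles for real data.

## Problem sizes and determinism

The test-suite and the acceptance script run entirely on synthetic data:
one 16 × 16 grid of 2000-sample curves for the clustering stage, 100
noisy single curves for recovery statistics, and 250 × 250 px images for
morphometry — sizes chosen to exercise every code path at interactive
speed. Every stochastic step (curve noise, per-cell draws, k-means
restarts) consumes an explicit seed; per-cell seeds are derived from the
grid's master seed, so grids are reproducible element-wise.

## Known limitations

* Curves must be breakthrough-type approach curves; retract adhesion and
  elasticity fitting are out of scope.
* Stacked-bilayer ruptures are only separated by the thickness window and
  the primary/secondary ranking, not by a dedicated model.
* The detector's `delta` is a force-scale parameter; data with noise
  above ~0.02 nN SD need a proportionally larger `delta` and will lose
  thin-membrane sensitivity accordingly.
* Real-image statistics (domain shrinkage percentages and the like)
  depend on instrument data; the package computes such summaries but
  ships no claims about their values.
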