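---
title: "Quantifying cortical actin wave dynamics with cortwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical actin wave dynamics with cortwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Giant *Dictyostelium discoideum* cells produce traveling waves of F-actin
polymerization on their basal membrane. Because the cells are much larger
than the waves, many waves coexist, and their areas, lifetimes, speeds and
propagation directions report on the state of the underlying excitable
signalling/cytoskeletal network — in particular on how close the system
sits to its activation threshold, and on how external cues such as a DC
electric field (EF) bias it. On nanoridged substrates (parallel ridges,
1.6 µm pitch) the waves are quasi-1D streaks guided along the ridge axis;
on flat substrates they expand as band-like fronts.

cortwave implements the full quantification chain for single-channel
(limE reporter) time-lapse movies:

1. **Optical flow** (`movie_flow()`): two-frame Lucas–Kanade flow with a
   Gaussian weight window, gated by a reliability score.
2. **Segmentation** (`segment_waves()`): intensity k-means for bright
   regions, intersection with the reliability mask, and division of
   composite structures whose edges move incoherently.
3. **Tracking** (`link_by_overlap()`): largest-overlap linking of
   per-frame components into wave tracks, with per-track duration, area,
   direction, and speed.
4. **Directionality** (`fit_bimodal_vm()`, `orientation_kymograph()`,
   `response_time()`): an antipodal bimodal von Mises mixture fitted to
   flow orientations in disjoint time windows.
5. **Morphometrics** (`fit_area_duration_boundary()`,
   `wave_dimensions()`, `occupancy_ratio()`, `spatial_profile()`,
   `front_back_split()`).
6. **Synthetic data** (`generate_movie()`): a ground-truthed movie
   generator, so every stage is testable without microscopy data.

All coordinates are `(x, y) = (column, row)` with the origin at the
top-left pixel; angles are measured in radians from `+x` toward `+y`
(rows increase downward) and reported in `[0, 2π)`. Lengths are in µm,
times in s.

## Optical flow and its reliability

Frames are pre-smoothed with a 2-D Gaussian (sd 3 px). For each pixel the
weighted least-squares flow equation is solved over a 19 × 19 window with
Gaussian weights of sd 2 px (0.42 µm at the default 0.21 µm/px
calibration). The *reliability* of a pixel is the smallest eigenvalue of
the weighted structure tensor `AᵀwA`: it is zero on textureless regions,
where the flow solve is rank-deficient.

Two gates are applied:

* **Validity** (`valid_mask`): reliability at or above a cutoff. The
  default cutoff is 0.1 × the 95th percentile of the movie's per-pixel
  reliabilities. This data-adaptive rule assumes waves (the textured,
  high-reliability objects) occupy at least a few percent of the movie's
  pixels, which holds for the dense wave fields the pipeline targets; for
  sparse movies, pass an explicit `reliability_threshold` in
  `lk_params()` (its units are squared intensity counts).
* **Orientation validity** (internal): a two-frame LK solve cannot report
  displacements beyond its own window half-width (9 px at defaults).
  Larger solutions arise where an object appears or vanishes between the
  two frames; they are excluded from every orientation statistic
  (mixture fits, kymographs, coherence decisions, speed clusters) but
  *not* from the segmentation validity mask, which by definition is
  eigenvalue-only — at a wave's death frame the reliability is high even
  though the flow direction is meaningless.

The reliability eigenvalue measures image structure, not motion: a
textured object that does not move still passes the validity gate.
`moving_mask()` therefore accepts an optional `min_magnitude` (px/frame)
when truly static bright objects must be suppressed; the default (0)
keeps the plain bright ∩ valid intersection.

## Segmentation and division of composite structures

Per frame, pixel intensities are clustered by k-means with k = 3
(background, dim halo, bright wave interior; fixed internal seed and 10
restarts make the result deterministic), and the brightest cluster is
intersected with the validity mask. Connected components (4-connectivity)
below 9 px — the scale below which the LK window cannot resolve flow
orientation — are discarded.

A large component may be two independent waves in contact. The decision
follows the flow at the component's two edge bands (the 2 px inward
boundary ring, split into halves by the principal axis): if the two
magnitude-weighted circular-mean orientations agree within π/2 the
component is one coordinated wave; otherwise it is cut. Weighting by
magnitude matters because vectors on a streak's long sides suffer the
aperture problem — near-zero magnitude, arbitrary orientation — and must
not vote. Each band must contribute at least 5 trustworthy vectors,
otherwise the component is kept intact (typically at the frame where a
wave dissipates).

The cut itself is a 1-D changepoint along the principal axis: vectors
aligned within π/4 of one edge mean vote for their side, and the cut is
placed at the centre of the cost-minimizing plateau. Within roughly half
a window of the internal boundary, LK output is a blend of both motions
(over a converging boundary with intensity pile-up it even inverts), so
per-pixel assignment is unreliable there; the changepoint localizes the
boundary to ~1 px on diverging composites. A curved internal boundary is
approximated by a straight cut — a known limitation.

## Tracking and wave speed

Components are linked across frames by largest pixel overlap (minimum
1 px), assignments resolved greedily in decreasing overlap order with
ties broken toward lower track ids; there is no gap closing, because a
gap would inflate the durations that enter the boundary fit. At a split
the largest fragment keeps the identity; at a merge the largest
contributor continues.

Wave speed groups a track's trustworthy flow vectors into orientation
clusters (circular single-linkage; an angular gap larger than π/4 starts
a new cluster), matches clusters across consecutive frames by nearest
mean orientation (within π/4), and takes the median centroid displacement
per frame. Matches whose centroid jump exceeds the LK window half-width
are rejected — a cluster cannot move farther per frame than the flow
could measure. The median (not mean) is robust to cluster birth/death
frames.

## Directionality: the antipodal bimodal von Mises mixture

Flow orientations pooled over disjoint 12-frame windows (2 min at 0.1
frames/s) are fitted with

  f(θ) = p₁ fVM(θ | μ₁, κ) + p₂ fVM(θ | μ₁ + π, κ),  p₁ + p₂ = 1,

i.e. two von Mises components constrained π apart with shared
concentration κ. The antipodal constraint reflects wave traffic running
both ways along a guidance axis. The likelihood is maximized by L-BFGS-B
from 8 equally spaced μ₁ starts (the surface has local optima), κ capped
at 500, with the label convention p₁ ≥ p₂. Vectors are unweighted by
magnitude. The *preferential direction* is the μ of the dominant
component.

Orientation kymographs histogram the same vectors in 36 bins of 10° per
window, rows normalized to proportions. The *response time* after an EF
reversal is the first window centre at which the preferential direction
falls within π/2 of the new cathode direction and stays there for 2
consecutive windows; the persistence requirement suppresses single-window
noise flips. `front_back_split()` lets the same machinery run separately
on the cell half facing the new cathode ("new front") and the half facing
the old one.

A note on degenerate fits: for uniform orientations the fitted κ
converges to 0 only like n^(−1/4) (the axial resultant scales as
n^(−1/2) and κ enters quadratically), so small samples show spurious κ̂
of a few tenths; the per-observation likelihood gain over the uniform
model is the meaningful diagnostic and is what the test suite checks.

## The area–duration boundary and the characteristic timescale

For an excitable system with lateral inhibition, the smallest area a wave
can reach grows exponentially with how long it survives:

  Area_min = C · exp(Duration / T).

`fit_area_duration_boundary()` groups waves by duration (durations are
inherently discrete on the 10 s frame grid; no binning), keeps the 5
smallest areas per duration, and fits log(area) against duration by
ordinary least squares; T = 1/slope. The per-wave area entering the fit
is the track's maximum area — the stable per-wave scalar. In
`run_pipeline()`, tracks whose maximum area never exceeds twice the
minimum component size are excluded first: they are debris at the
segmentation resolution limit and would otherwise sit below the true
envelope. The reference timescales for validation are 48 s (no EF) and
61 s (with EF), the two conditions the package's acceptance script
regenerates and refits.

## What the synthetic generator emulates — and what it does not

`generate_movie()` renders the study conditions: waves nucleate as a
Poisson process (default 1.2 nucleations/frame, keeping wave occupancy at
a few percent of the frame, which also anchors the adaptive reliability
cutoff); directions follow the antipodal bimodal von Mises law; speeds
are ~0.04 µm/s (≈2 px/frame at 0.21 µm/px and 10 s/frame); lifetimes are
geometric on the frame grid (memoryless death — an excitable patch
dissipating with constant hazard; mean 4 frames, capped at 10 for
rendering, mean 5 capped at 12 for population draws); each wave's area is
the boundary value C·e^(D/T) times a log-exponential scatter factor ≥ 1
(rate 6), so the population's lower envelope traces the boundary and the
five-smallest estimator is approximately unbiased. Ridged streaks are 5
px wide, elongated along the ridge axis, and nucleate with their axis
snapped to the 1.6 µm ridge grid; flat waves are 3:1 bands elongated
perpendicular to their motion. Waves die at their drawn death, at the
movie edge, or when they would cross the cell boundary.

Rendering: the binary mask carries a static per-wave speckle texture
(Gaussian-correlated, sd 0.8 px, 20% amplitude — F-actin puncta at the
diffraction scale, giving wave interiors trackable structure), is blurred
with a Gaussian PSF (sd 1 px), scaled to the signal amplitude (default
1500 counts over a 500-count background; the paper does not quantify
wave-to-background contrast, so this is a free parameter), and corrupted
with additive Gaussian noise (sd 50 counts; EMCCD movies at these
intensities are well approximated by additive noise, and no stage assumes
a noise law). Frames are rounded to integer counts, so a written TIFF
round-trips bit-exactly and a fixed seed gives bit-identical output.

Not emulated: reaction–diffusion wave physics (no refractory collisions,
no U-turn curvature), photobleaching, stage drift, multi-channel imaging,
non-disk cell shapes, and wave–wave exclusion (overlapping waves simply
add intensity). Passing tests on this generator therefore demonstrate
that the *measurement chain* recovers known kinematics and population
laws under realistic imaging conditions — not that it would be robust to
every pathology of real microscopy.

## Problem sizes and numerical choices

Validation movies are 192 × 192 px × 72–96 frames with a 80.6 px cell
radius — small enough that the full suite runs in a couple of minutes
while every stage still operates in its intended regime. Population-level
fits use 1000 waves. Key numerical choices: reflective boundary handling
in all convolutions; central differences for spatial gradients and the
two-frame difference for the temporal gradient; pixels with singular
structure tensors get zero flow and zero reliability; k-means on fewer
than k distinct intensities is treated as "no waves" inside the pipeline
(and is an error when called directly); the boundary fit refuses
non-positive slopes and fewer than 3 distinct durations; ties in
preferential direction (p₁ = p₂) return μ₁.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates, from scratch and under a given seed,
a 1000-wave population for each condition (C = 10 µm², T = 48 s and
61 s), refits the boundary, and writes the recovered timescales as JSON.
Typical recovery is within ~1–2% of the generating value; the test suite
holds it to 10%.
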