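---
title: "Transmural orientation analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmural orientation analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroalign)
```

## The problem

During rapid growth of the embryonic ventricular wall, both the coronary
microvasculature and the surrounding cardiomyocytes organize into layered,
helically wound patterns between the epicardium (outer surface) and the
endocardium (inner surface). `coroalign` quantifies that organization from
two complementary data streams:

* **vessel skeleton graphs** — centerline representations (nodes, segments,
  ordered points, coordinates in microns) exported by auto-skeletonization
  of segmented 3D vascular images, and
* **nuclei image z-stacks** — 2D grayscale images of elongated
  cardiomyocyte nuclei acquired at increasing depth.

Both are reduced to *depth profiles* of orientation — mean angle,
concentration and uncertainty as a function of distance from the epicardial
surface — which can then be overlaid across hearts and correlated with one
another.

## The surface-anchored frame and vessel angles

Every vessel segment is assigned one local orthonormal triad at its
polyline midpoint:

* `g1` — the unit vector from the vessel point toward its nearest
  epicardial surface point; the distance itself is the segment's *depth*;
* `g2 = g1 x (V_AB x g1)`, normalized — the manually identified apex-to-base
  axis `V_AB` projected onto the surface tangent plane;
* `g3 = g2 x g1` — the circumferential direction.

The operand order of the final cross product fixes the handedness of the
frame; flipping it would negate every helical angle, so it is applied
exactly as written throughout.

The segment vector `V_v` (start node to end node) yields two angles:

* **helical angle** `alpha_H = 90° − acos(V_v·g2 / |V_v|)` — elevation out
  of the circumferential–radial plane; 0° is circumferential, ±90° is
  longitudinal (apex–base);
* **projection angle** `alpha_P` — the angle between the tangent-plane
  projection `V_p = g1 x (V_v x g1)` and `g3`, reported signed and folded to
  (−90°, 90°] for direct comparison with 2D nuclei orientation.

Two conventions deserve comment. First, skeleton node order is arbitrary,
and the elevation formula flips sign when a segment is traversed backwards
— a sign change that angle doubling does *not* absorb. Segments are
therefore canonicalized to a non-negative circumferential component
(`V_v·g3 ≥ 0`, tie toward `V_v·g2 ≥ 0`) before the formula is applied,
which makes the helical angle a property of the undirected centerline and
makes direction-reversal invariance exact. Second, the arc-cosine form of
the projection angle is sign-blind; it is computed as
`atan2(V_p·g2, V_p·g3)` instead, which has the same magnitude and carries
the sign needed when a vessel profile is correlated against a signed nuclei
profile.

Degenerate cases — a vessel point coinciding with a surface point, `g1`
parallel to the apex–base axis, zero-length or surface-normal segments —
are flagged and excluded from angle statistics with counts reported, rather
than letting NaNs propagate into circular means.

The nearest-surface search runs on a uniform grid spatial index (cells
sized from the cloud density, candidate cells limited to those intersecting
a ball bounded by a coarse-subsample distance). Its results are exact: unit
tests assert equality with exhaustive search, including ties, which resolve
to the lowest surface-point index for determinism.

## Nuclei orientation from the Fourier angular amplitude

Each slice is mean-subtracted, tapered with a Hann window (suppressing the
±45° cross artifact that hard image borders would otherwise inject into
wedge sums), and Fourier transformed. The squared modulus of the spectrum
is summed under wedge masks of width 5° (configurable) that partition the
frequency half-plane; each non-DC bin belongs to exactly one wedge,
boundary ties to the lower angle, and wedges are restricted to the
inscribed frequency disk because on a square grid diagonal wedges would
otherwise contain more bins and inflate the amplitude at ±45°. A texture
elongated at spatial angle θ concentrates power at θ + 90° in frequency
space; that rotation is applied internally so all reported angles are
image-space orientations. The resulting angular amplitude `A(θ_i)` is
normalized so its minimum is zero and its area over θ (in radians) is one.

The slice orientation is the axial circular mean of the wedge centers
weighted by `A(θ_i)`; the concentration is fitted as described below; slice
depth is the slice-center z. Analysis is strictly 2D per slice — no nucleus
instance segmentation and no 3D orientation recovery is attempted.

## Axial circular statistics

Orientations are axial (θ and θ + 180° are the same line). Means use angle
doubling: each orientation is doubled, unit phasors are averaged (optionally
weighted), and the mean is half the argument of the resultant, folded to
(−90°, 90°]. The resultant length `R` flags degenerate sets: equal mass at
0° and 90° doubles to antipodal phasors, `R = 0`, and the mean is reported
as undefined rather than arbitrary.

Dispersion is described by the bimodal von Mises density with antipodal
modes,

$$f(\theta) = \frac{e^{\kappa\cos(\theta-\mu)} + e^{\kappa\cos(\theta+\pi-\mu)}}
{2\pi I_0(\kappa)},$$

evaluated in an exponent-shifted form stable to large κ. This density has
period π and unit mass on any half-period, which is the natural axial
normalization; all fits and uncertainties treat it as a density on
(−90°, 90°]. At κ = 0 it is the uniform axial density 1/π; for large κ it
approaches a Gaussian with variance 1/κ.

The concentration is estimated by least squares between an angular density
and this pdf with the mean held fixed — for vessel windows, the empirical
density of angles histogrammed on the same 5° grid as the spectra; for
nuclei, the normalized `A(θ_i)` itself. (Comparing *angles* to pdf values
would be dimensionally inconsistent; the density-vs-pdf reading is the only
coherent one and is adopted throughout.) The minimization runs a coarse
log-spaced bracket scan followed by golden-section refinement on
κ ∈ [0, 10⁴], with boundary solutions flagged.

Error bars use the **standard uncertainty** `u`: the half-width such that
the axial pdf centered at the mode carries 68% of its mass on (−u, u),
found by root-finding with adaptive quadrature to 10⁻¹⁰ radians. This
replaces the standard deviation, which is ill-defined for bimodal circular
distributions: `u` is well defined for every κ ≥ 0, equals
0.68 × 90° = 61.2° in the uniform limit, decreases strictly with κ, and
approaches the Gaussian standard deviation 1/√κ for large κ.

## Depth profiles, local fields, and comparisons

* **Moving-window profile** — at evaluation depths every 5 μm (well below
  the window width; the step is not stated by the windowing itself),
  all segments whose midpoint depth lies within ±15 μm are pooled; each
  window reports the axial mean, fitted κ, `u`, and count. Windows with
  fewer than 10 segments are flagged, not interpolated: κ fits on fewer
  axial samples are unstable. Segments count once each (the circular mean
  averages unit vectors with equal weight); an optional length-weighted
  mode exists. No radius-based exclusion of large vessels is applied by
  default.
* **Local angle field** — per segment, the axial mean over all segments
  whose midpoints fall in an axis-aligned box (default 136 × 136 × 175 μm,
  image-axis aligned) centered on its midpoint, for color-coded rendering
  exports.
* **Depth normalization** — an affine map of depth to [0, 1] between the
  shallowest and deepest sampled segments, letting walls of different
  thickness be overlaid.
* **Profile correlation** — both mean-angle series are restricted to their
  overlapping depth range, unwrapped (axial jumps above 90° continued by
  ±180°, since profiles legitimately pass through the ±90° fold), linearly
  interpolated onto 200 common depths, and compared by Pearson correlation.
* **Density** — vessel volume fraction (foreground voxels over ROI voxels,
  membership by voxel center) and length density (polyline length clipped
  to the ROI by linear interpolation at its faces, in mm, over ROI volume
  in mm³). All internal lengths are microns; conversion to mm-based units
  happens exactly once, at reporting.
* **Group comparison** — one-tailed F-test on variances (larger variance in
  the numerator) followed by a two-tailed Welch T-test, both delegated to
  the standard distribution functions; no multiple-testing correction.

## What the synthetic phantoms emulate

The generator provides ground truth for every stage under the study
conditions: slab walls (700 × 700 μm patch) as the exact-geometry sanity
case, and hemispherical shells approximating the newly septate and
end-of-compaction ventricle (wall thickness 550 μm with 800 μm outer
radius, and 900 μm with 1200 μm, respectively). Segment midpoints are
uniform in the wall; in-tangent-plane directions are drawn from the bimodal
von Mises distribution around a transmural mean profile — linear from −30°
at the epicardium to +80° at the endocardium by default, or a piecewise
layered preset — with constant or depth-dependent κ (default 8). Node order
is randomized to exercise axial folding. Surface clouds are lattices
(slab) or Fibonacci sphere bands (shell) at 5 μm spacing; on the slab,
midpoints snap laterally to the surface lattice so frames are exact and
slab identities hold to machine precision. Masks are rasterized as
flat-capped cylinders so the analytic foreground volume of non-overlapping
segments is exactly πr²L.

Nuclei phantoms render ~150 anti-aliased 12 × 3 μm ellipses per
360 × 360 μm slice at 1 μm/pixel, orientations drawn around a profile
rotating from −40° to +79° across the wall (the counterclockwise rotation
reported for the embryonic left ventricular wall), with additive Gaussian
noise. Truth tables record both the profile value and the realized mean of
the drawn orientations per slice.

The phantoms deliberately omit much of real data's structure: vessels are
straight, unconnected segments rather than branching networks; there is no
out-of-plane tilt by default, no image-formation model beyond soft edges
and additive noise, no intensity attenuation with depth, and no nuclei
crowding or overlap statistics. Passing recovery tests therefore
demonstrates correctness of the geometry and statistics under the assumed
generative model, not robustness to segmentation artifacts or optical
degradation in real stacks.

## Numerical choices and degenerate inputs

* All angle arithmetic is in radians internally, degrees at interfaces.
* Frames are orthonormal to 10⁻⁹; triads failing that are a bug, not data.
* Nearest-surface ties break to the lowest surface point index; wedge and
  histogram boundary ties go to the lower angle bin.
* The area normalization of `A(θ_i)` uses radians (area 1 over π), matching
  the axial pdf's half-period mass.
* Zero-thickness walls, empty ROIs, non-overlapping profiles, constant
  images and empty foregrounds raise classed errors
  (`coroalign_config_error`, `coroalign_format_error`, ...), never silent
  NA results.
* Profile evaluation depths, window memberships and generator draws are
  deterministic given the seed; identical specs and seeds reproduce outputs
  bit for bit.

## Known limitations

* The min-zero normalization of the angular amplitude imposes a noise floor
  on fitted κ for (near-)isotropic images: subtracting the minimum of a
  flat spectrum rescales its sampling noise to unit area, so pure white
  noise fits to κ of order 0.5–1 rather than 0. The resultant length `R`
  is the reliable isotropy indicator in that regime; κ values from
  near-isotropic slices should be read accordingly.
* Fits of κ from min-zero-normalized spectra are slightly biased upward
  relative to sample-based fits, because the true pdf's minimum is positive.
* The wall "layers" discussed for embryonic hearts are not detected
  automatically; the package exports κ(depth) and leaves layer boundaries
  to the user.
* Helical angles use the printed elevation formula on the full 3D vector;
  for strongly out-of-plane vessels the projection angle is the quantity
  comparable with 2D nuclei orientation.

## Problem sizes used in validation

The test suite validates end-to-end recovery on a 2,000-segment shell
phantom (±15 μm windows, bins with n ≥ 30 recovered within ±5°), a
16-slice nuclei stack (per-slice error ≤ 6°, profile correlation ≥ 0.98
against realized truth), co-alignment of 1,500-segment vessel and nuclei
phantoms sharing one orientation field (ρ ≥ 0.95), density metrics against
analytic values (length density exact, rasterized volume fraction within
10%), κ recovery within 25% (median over 100 replicates of n = 500 at
κ ∈ {2, 8, 32}), and the 68% coverage of `u` verified by independent
quadrature to 10⁻⁴ for κ ∈ {0, 1, 10, 100}. These sizes were chosen as the
smallest at which window counts and fit stability match the assumptions
above (n ≥ 30 per reported bin, n ≥ 500 per κ fit).
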