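# coroalign

Quantitative analysis of how coronary microvessels and cardiomyocyte
nuclei are oriented across the ventricular wall.

During embryonic development the heart wall thickens rapidly, and both the
coronary microvasculature and the surrounding cardiomyocytes organize into
helically wound layers between the epicardium and the endocardium.
`coroalign` measures that organization from the two data streams such
studies produce — vessel centerline skeletons extracted from segmented 3D
image stacks, and 2D image z-stacks of elongated nuclei — and reduces both
to comparable transmural orientation profiles.

## What it computes

**Vessels.** Each skeleton segment gets a local orthonormal frame anchored
to the epicardial surface: `g1` points toward the nearest surface point
(its distance is the segment's depth), `g2 = g1 × (V_AB × g1)` is the
apex-to-base axis projected on the tangent plane, and `g3 = g2 × g1` is
circumferential. The segment vector `V_v` then yields the helical angle
`α_H = 90° − acos(V_v·g2/|V_v|)` (0° circumferential, ±90° longitudinal)
and the signed projection angle `α_P` between its tangent-plane projection
and `g3`.

**Nuclei.** Each slice's orientation is measured texture-wise from the 2D
Fourier transform: the power spectrum is summed under 5° wedge masks
`A(θ_i) = Σ |F(k_x, k_y)|² h_θi(k_x, k_y)`, rotated back to image space,
and normalized to minimum zero and unit area.

**Statistics.** Orientations are axial (θ ≡ θ + 180°), so means use angle
doubling, and dispersion is described by the bimodal von Mises density

```
f(θ) = [exp(κ·cos(θ−μ)) + exp(κ·cos(θ+π−μ))] / (2π I₀(κ))
```

with concentration κ fitted by least squares against the empirical angular
density (or the normalized spectrum). Error bars use the standard
uncertainty `u`, the half-width containing 68% of the axial density's mass
— well defined at any κ, 61.2° in the uniform limit, → 1/√κ for large κ.

Orientation-versus-depth profiles use a ±15 μm moving window; profiles can
be depth-normalized to [0, 1] across the wall, exported as CSV, and
correlated (after axial unwrapping and resampling to 200 common depths) by
Pearson's ρ. Vessel density is reported as volume fraction and length
density (mm⁻²); groups are compared by an F-test then a Welch T-test.

A synthetic phantom generator (slab and hemispherical-shell walls with
prescribed orientation profiles; ellipse-rendered nuclei stacks) provides
ground truth for end-to-end validation of every stage.

## Worked example

Generate a shell-wall phantom whose mean helical angle rotates linearly
from −30° at the epicardium to +80° at the endocardium (κ = 8), run the
vessel pipeline, and recover the transmural profile:

```r
library(coroalign)

ph <- make_wall_phantom(wall_phantom_spec("ed9", n_segments = 2000,
                                          kappa = 8, seed = 11))
va <- vessel_angles(ph$graph, ph$surface, ph$config)
prof <- depth_profile(va$helical_deg[!va$excluded],
                      va$depth[!va$excluded], half_width = 15)
head(as.data.frame(prof)[!prof$flagged, ], 4)
#>   depth mean_angle_deg kappa u_deg   n flagged
#> 1 15.28         -25.08 6.977 22.14  64   FALSE
#> 2 20.28         -26.04 7.001 22.10  88   FALSE
#> 3 25.28         -24.03 7.360 21.53 108   FALSE
#> 4 30.28         -22.89 6.672 22.67 125   FALSE
```

Each row is one ±15 μm window: depth in microns from the epicardial
surface, the axial circular mean helical angle (negative = wound clockwise
of circumferential, rising toward +74.7° at 525 μm depth in this phantom),
the fitted von Mises concentration (≈ 7–8, matching the generating κ = 8),
the 68% standard uncertainty, and the segment count. The nuclei pipeline
produces the same profile structure per slice, and the two streams can be
compared after depth normalization:

```r
ns <- make_nuclei_stack(nuclei_phantom_spec(seed = 7))
np <- nuclei_depth_profile(ns$stack)
vp <- depth_profile(va$projection_deg[!va$excluded],
                    va$depth[!va$excluded], half_width = 15)
correlate_profiles(normalize_depth(vp, range(va$depth)),
                   normalize_depth(np, range(np$depth)), 200)$rho
#> [1] 0.9960
```

ρ close to 1 indicates the vessel projection angles and the nuclei
orientations rotate together across the wall.

A command-line wrapper for the same operations
(`simulate`, `vessels`, `nuclei`, `density`, `correlate`) ships at
`inst/scripts/coroalign.R`.

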