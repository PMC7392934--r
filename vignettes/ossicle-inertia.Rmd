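---
title: "Methods: voxel inertia, ossicular morphometry and the middle-ear transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel inertia, ossicular morphometry and the middle-ear transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossimetrics)
```

## The problem

At low frequencies the mammalian malleus–incus complex rotates about a
hinge-like anatomical axis running through the anterior process of the
malleus and the tip of the incus short process. Two families of quantities
govern this mechanism. First, *inertial* ones: the moments of inertia of
the ossicles about that axis and about the anatomical directions, which act
for rotation the way mass acts for translation. Second, *transformer* ones:
the tympanic-membrane/footplate area ratio and the ossicular lever ratio,
which together set how well the ear matches the high specific acoustic
impedance of cochlear fluid to that of air. `ossimetrics` computes both
families from segmented micro-CT volumes, surface meshes and anatomical
landmarks, and provides a phantom generator with closed-form ground truth
so the entire chain can be validated without scan data.

Units are fixed package-wide — mm, mm², mm³, mg, mg·mm², mg/mm³,
Pa·s·m⁻¹ — matching the scale of the organ (ossicles are 2–8 mm long and
1–30 mg).

## Voxel mass properties

A segmented volume is a `voxel_volume`: a 3D array indexed `(x, y, z)` with
isotropic spacing `s`; the world position of voxel `(i, j, k)` is
`origin + (i−1, j−1, k−1)·s` at the voxel *centre*. Grayscale levels use
the dimensionless 0–1000 convention (0 = no attenuation, 1000 = maximum);
`segment_window()` applies the conventional 250–1000 bone window. An empty
segmentation is suspicious but legal, so it warns rather than errors.

`mass_properties_from_mask()` uses the standard point-mass discretisation:
each occupied voxel contributes a point mass `m_v = ρ s³` at its centre, so

* `V = N s³`, `m = ρ V`, COM = mean of occupied centres,
* `I_COM = Σ m_v (‖r‖² 𝟙 − r rᵀ)` with `r` relative to the COM,
* principal moments/axes from a symmetric eigen-decomposition, sorted
  ascending `I_MIN ≤ I_MED ≤ I_MAX`.

An optional `cube_correction` flag adds each voxel's own solid-cube inertia
(`+ m_v s²/6` on the diagonal). It is off by default: both variants
converge to the continuum limit as `s → 0`, the point-mass form is the
conventional one for this kind of data, and a stated default matters more
than the (second-order) difference.

**Eigenvector conventions.** Eigenvectors are sign-ambiguous, and degenerate
spectra (a sphere) make whole eigenspaces ambiguous. For reproducible
regression tests each axis is flipped so its largest-magnitude component is
positive (ties broken by the first nonzero component) and the determinant
is forced to +1 by flipping the third axis. When two principal moments
agree to better than one part in 10⁶, tests compare moments only, never
axes.

**Axis transport.** `moment_about_axis()` evaluates
`nᵀ I_COM n + m d²` — the parallel-axis theorem — for any axis; this is
exact, not discretised, once `I_COM` is known. The brute-force per-voxel
oracle `brute_force_inertia()` recomputes `Σ m_v d_⊥²` directly and agrees
with the tensor route to ~1e-9 relative; it exists purely as an
independent check and is what the property tests compare against.

**Low-density interiors.** Real ossicles contain marrow spaces and vessels.
The package's convention assigns them zero mass: the mask is the bone
phase. The sensitivity of that choice is quantified by
`density_correction()`:
`ρ_H = (m − v_L ρ_L V)/((1 − v_L) V)`, and
`density_correction_factor()` reports the *relative* increase of the
zero-mass estimate over the `ρ_L` estimate, normalised by the zero-mass
estimate — algebraically `v_L ρ_L V / m`. For a 22.9 mg, 10.4 mm³
ossicular chain this is 0.45 % at `v_L = 1 %` and 0.91 % at `v_L = 2 %`
with water-density interiors — small, which is what justifies the zero-mass
default.

```{r density}
signif(density_correction_factor(22.9, 10.4, 0.01, rho_L = 1), 2)
signif(density_correction_factor(22.9, 10.4, 0.02, rho_L = 1), 2)
```

**Composites.** `combine_bodies()` implements standard rigid-body addition
(masses and volumes add, COM mass-weighted, tensors transported to the
joint COM by the tensor parallel-axis rule) for the malleus–incus complex
and the entire chain.

## Morphometry

Characteristic lengths are plain Euclidean distances between named
landmarks (`L_mal` head tip→umbo tip, `L_manu` lateral-process tip→umbo
tip, COM-anchored `L_head`, `L_umbo`, `L_SP`, `L_LP`). Landmark sets carry
an ear side; left ears are mirrored (`x → −x`) to a right-ear convention at
load time with the flip recorded, so all frame logic downstream assumes a
single handedness and right ears yield right-handed stapes frames.

Patch areas are triangle sums; centroids are area-weighted. Plane fits are
total-least-squares: the normal is the smallest-eigenvalue direction of the
*exact* area-weighted second-moment matrix of the surface (integrated per
triangle, not sampled at vertices), so the fit is independent of
tessellation density.

**Projected area.** A curved or folded patch projected onto a plane can
cover the same planar region twice; summing projected triangle areas would
double-count. `projected_area()` therefore rasterises the projected
triangles on a regular grid and counts covered pixels once. The default
pixel is 1/200 of the shorter projected bounding-box extent — fine enough
that a hemisphere's equatorial projection is within 1 % of `πr²` — and the
result is capped by the exact sum of projected triangle areas (an upper
bound on the union), which also makes planar patches exact and guarantees
`A_proj ≤ A`.

**Stapes frame.** Origin at the footplate medial-surface centroid; ẑ = the
fitted plane normal signed toward the stapes head (lateral); x̂ = the long
in-plane axis, taken as the principal direction of the area-weighted 2D
second moments of the projected footplate (the operationalisation of the
footplate "long axis" is a package choice — it is robust, rotation
invariant and matches the long/short-axis language); ŷ = ẑ × x̂.
Footplate lengths `a, b` are extents along x̂, ŷ; `h` is the
footplate-to-head centroid distance, and `h_c` is defined as the Euclidean
distance from the footplate centroid to the COM (not its ẑ-component).

**Hinge and levers.** `hinge_axis()` is the sign-normalised line through
the two tether landmarks; `L1`, `L2` and the axis–COM distance are
perpendicular point-to-line distances, and the lever ratio is `L1/L2`.
Because per-specimen ratios and ratios of group means differ slightly,
`aggregate_records()` averages ratios as mean-of-ratios (matching ± SD
reporting on ratios) and `species_ratio()` reports ratio-of-means
separately, labelled as such.

## Transformer acoustics

The ideal-transformer model composes four scalars:

| quantity | formula | default |
|---|---|---|
| area ratio | `A_TM / A_FP` | — |
| pressure gain | `area ratio × L1/L2` | — |
| motion ratio | `20 log10(L1/L2)` dB | — |
| TM impedance | `Z_cochlea / (area ratio × (L1/L2)²)` | `Z_cochlea` = 56 kPa·s·m⁻¹ |
| energy fraction | `4 Z_air Z_TM / (Z_air + Z_TM)²` | `Z_air` = 420 Pa·s·m⁻¹ |

The projected footplate area is the default for `A_FP` (it is the area the
oval window presents to the piston-like motion component). `Z_cochlea` is a
scalar: frequency dependence of cochlear input impedance is out of scope.
The energy fraction is the standard two-medium power-transmission
coefficient — symmetric, in (0, 1], equal to 1 iff matched.

```{r transformer}
print(species_report(), digits = 3)
```

## The phantom generator

Phantoms are unions of analytic solids (spheres, ellipsoids, cylinders,
boxes) tagged bone or low-density; closed-form volume/COM/inertia per
primitive plus the parallel-axis rule give exact ground truth, with
low-density inclusions composed at negative mass (they must lie inside
bone, and bone primitives must not overlap — the builders are laid out to
respect this). A voxel is occupied iff its *centre* is inside a solid,
matching the point-mass discretisation so the voxel-vs-analytic bias stays
second order. Grayscale levels 0/600/100 (background/bone/inclusion) make
the 250–1000 window reproduce the bone mask exactly.

`toy_ossicle()` assembles ossicle-like bodies — sphere head + slender
handle (malleus), body + two processes (incus), plate + crura + head
(stapes), or the chain — with construction dimensions near published
sheep/human means (sheep: `L_mal` 7.88 mm, `L_manu` 5.26 mm, footplate
2.03 × 0.93 mm, `h` 2.10 mm, lever arms 4.16/1.69 mm). Landmark-derived
truths (`L_mal`, `L1`, `L2`, lever ratio) are exact by construction;
voxel-derived ones carry the discretisation error of the chosen spacing.
The toys default to 0.05 mm spacing — coarser than raw micro-CT (6–15 µm)
but fine enough for ~1 % inertia accuracy at a grid a laptop test suite can
afford; the acceptance properties push a single ellipsoid to 3.125 µm
(≈8.8 M voxels) to demonstrate sub-1 % convergence. A `jitter` argument
perturbs dimensions log-normally (seeded, bit-reproducible) to emulate a
specimen cohort.

What the phantoms deliberately do **not** emulate: trabecular texture,
scanner noise and beam hardening, partial-volume grayscale gradients, the
true curved shapes of ossicles, or a physically articulated
incudostapedial joint. Passing tests therefore validate the *mathematics*
of the pipeline (discretisation, frames, transport, projection) and its
conventions — not segmentation quality on real scans, nor the anatomical
fidelity of any particular specimen.

## Numerical choices and degenerate inputs

* TIFF carries no spacing — it must be supplied; NRRD spacing is read from
  the header, and anisotropic spacing is a hard error (the pipeline
  assumes isotropic voxels). TIFF pages are stored as 32-bit floats at
  `level/1000`.
* STL reading welds duplicated vertices at 1e-7 mm and drops zero-area
  faces; enclosed volume checks orientation and rejects inward-facing
  meshes.
* Collinear patches cannot define a plane → error; a stapes head centroid
  in the footplate plane cannot sign ẑ → error; coincident hinge
  landmarks, or an umbo/ISJ centroid lying exactly on the axis, make the
  lever ratio undefined → error (an axis–COM distance of zero is allowed).
* Species average density follows the measured-mass convention: mean mass
  over mean volume (`resolve_density()`), not the mean of per-specimen
  densities.
* Reports keep full precision; rounding happens only at presentation.

## Problem sizes and limitations

The test suite runs ≈300 assertions in about a minute on one CPU: toy
ossicles at 0.05–0.08 mm spacing (10⁴–10⁵ voxels), the convergence ladder
at 12.5/6.25/3.125 µm on a single ellipsoid, ten random phantom/axis pairs
for oracle agreement, and 500 sampled directions for the minimum-moment
property.

Known limitations: no native SCANCO AIM or DICOM reading (convert to
TIFF/NRRD first); no automatic landmark detection; no grayscale-calibrated
non-uniform density; no frequency-resolved middle-ear transfer function —
the transformer block is the static, ideal-transformer idealisation, whose
well-known limitations apply.
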