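# ossimetrics

Quantitative middle-ear mechanics starts from three small bones. How hard
the malleus–incus complex resists the hinge-like rotation that drives
hearing at low frequencies is set by its mass distribution — its moments of
inertia about the anatomical rotational axis — and how well the ear couples
airborne sound into cochlear fluid is set by two anatomical ratios: the
tympanic-membrane/footplate area ratio and the ossicular lever ratio.
`ossimetrics` implements this computational chain for segmented micro-CT
data, for researchers in comparative auditory biomechanics:

* **Voxel mass properties** — volume, mass, centre of mass (COM), the
  inertia tensor and its principal decomposition from a binary bone mask,
  with every occupied voxel a point mass at its centre:
  `I = ∫ r² dm ≈ Σᵢ mᵥ rᵢ²`, transformed to arbitrary axes by the
  parallel-axis theorem `I = I_COM + m d²`. A density sensitivity utility
  quantifies the effect of low-density interior tissue:
  `ρ_H = (m − v_L ρ_L V) / ((1 − v_L) V)`.
* **Morphometry** — characteristic lengths from named landmarks, articular
  and footplate patch areas and centroids, total-least-squares footplate
  plane fits, overlap-safe projected areas, equivalent diameters
  `d = √(4A/π)`, the footplate-based stapes frame, the hinge axis through
  the malleus anterior process and incus short-process tip, and the lever
  arms `L1` (axis→umbo) and `L2` (axis→incudostapedial centroid).
* **Transformer acoustics** — area ratio `A_TM/A_FP`, pressure gain
  `(A_TM/A_FP)·(L1/L2)`, motion ratio in dB `20·log10(L1/L2)`,
  ideal-transformer tympanic-membrane impedance
  `Z_TM = Z_cochlea / ((A_TM/A_FP)·(L1/L2)²)` and the two-medium
  power-transmission fraction `T = 4·Z_air·Z_TM/(Z_air + Z_TM)²`.
* **Synthetic phantoms** — ossicle-like solids assembled from analytic
  primitives with closed-form mass properties, landmarks and lever truth,
  so the whole chain is testable without scan data.
* **Pipeline** — per-specimen records, mean ± SD species summaries and
  cross-species ratio columns.

Formats: multi-page TIFF and NRRD volumes, ASCII/binary STL meshes,
JSON/CSV landmarks, YAML parameter files. Units throughout: mm, mm², mm³,
mg, mg·mm², Pa·s·m⁻¹.

## Worked example

```r
library(ossimetrics)

# a sheep-scale toy ossicular chain with analytic ground truth
fx <- toy_ossicle("chain", "sheep", seed = 1)
mp <- mass_properties_from_mask(fx$mask, density = 2.2)
summary(mp)
#>                V                m              rho            I_MIN
#>          10.6400          23.4100           2.2000          32.5300
#>            I_MED            I_MAX I_MIN_over_I_MAX I_MED_over_I_MAX
#>         111.8000         128.3000           0.2536           0.8712

# lever geometry about the hinge axis
hx  <- hinge_axis(get_landmark(fx$landmarks, "anterior_process"),
                  get_landmark(fx$landmarks, "short_process_tip"))
lever_geometry(hx, get_landmark(fx$landmarks, "umbo_tip"),
               get_landmark(fx$landmarks, "isj_centroid"), com = mp$com)
#> <lever_geometry> L1 4.16 mm, L2 1.69 mm, lever ratio 2.462
#>   axis-to-COM distance 0.236 mm

# impedance matching for the default sheep/human parameter sets
print(species_report(), digits = 3)
#>   species area_ratio lever_ratio pressure_gain lever_db Z_TM energy_fraction
#> 1   sheep       30.5        2.47          75.3     7.85  301           0.973
#> 2   human       23.9        1.25          29.9     1.94 1501           0.683
```

The summary row reads: the sheep ossicular chain toy has volume 10.6 mm³
and mass 23.4 mg; its smallest principal moment is well below the largest
(ratio 0.25), i.e. the mass is concentrated near one axis. The lever table
reads: the sheep ear trades a 2.47× umbo-to-lenticular motion step-down
(7.85 dB) for a pressure gain of ≈75, which transforms the 56 kPa·s·m⁻¹
cochlear impedance down to ≈301 Pa·s·m⁻¹ at the tympanic membrane — close
to air's ≈420 Pa·s·m⁻¹, so ≈97 % of incident sound energy is accepted;
the human parameter set accepts ≈68 %.

A thin CLI wraps the same functions
(`inst/cli/ossimetrics.R segment|inertia|transformer|synth`).

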