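---
title: "Voxel-based finite element damage kinetics in bast fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based finite element damage kinetics in bast fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bast fibers (hemp, flax) owe much of their mechanical variability to
defects: machined or natural surface notches, surface roughness left by
decortication, and the lumen — the tubular cell cavity that runs the full
length of the fiber. High-resolution X-ray micro-tomography images these
features at sub-micrometer voxel sizes, and a voxel-based finite element
(FE) model can then predict where tensile damage starts and how it
spreads. `fibrekin` implements that chain end to end: synthetic tomogram
generation (because real tomograms of this kind are rarely deposited),
segmentation and morphometrics, voxel-to-hexahedron meshing with a binary
gray-level material law, a linear elastic tensile solve, iterative
stress-criterion damage accumulation, and kinetics characterization.

# Model and assumptions

**Geometry.** The image is a 3D gray-level array with isotropic voxel
size; the first array axis X is the fiber longitudinal axis and the
loading axis. After segmentation only two gray levels remain: 0 (air) and
255 (solid).

**Material law.** Every solid voxel becomes one 8-node trilinear
hexahedral element carrying the solid-phase constants \(E_0\) (Young's
modulus, MPa) and \(\nu_0\) (Poisson ratio). Air voxels are not meshed —
the binary mapping \(E = E_0\,\delta,\ \nu = \nu_0\,\delta\) with
\(\delta \in \{0, 1\}\) is realized by meshing only the \(\delta = 1\)
phase. The constitutive model is linear isotropic elasticity; anisotropy
and inelasticity of the cell wall are out of scope.

**Boundary conditions.** Grip-type ("glued-end") tension:
\((U_x,U_y,U_z)_{x=0} = (0,0,0)\) and \((U_x,U_y,U_z)_{x=L} = (U,0,0)\).
The lateral constraint at \(x=L\) deliberately suppresses Poisson
contraction at the grip, as in the glued-card tensile configuration. The
nominal strain is \(\varepsilon = U/L\).

**Damage.** At each load increment the elastic problem is solved once,
a scalar criterion is evaluated per element — stress intensity
\(S_I = S_1 - S_3\), largest principal stress \(S_1\), the normal
components \(\sigma_{XX}, \sigma_{YY}, \sigma_{ZZ}\) (signed;
tension-driven), or the shear components
\(|\sigma_{XY}|, |\sigma_{XZ}|, |\sigma_{YZ}|\) — and the
highest-stressed elements are *converted to the ground level*: their
modulus drops to \(10^{-6} E_0\) while they stay in the mesh, keeping the
system matrix well posed. Damage is irreversible. The damage ratio is the
cumulative number of damaged elements over all damageable (solid)
elements.

# The damage quantum: strength rule vs fraction rule

Two conversion rules are provided, because the phrase "the elements of
the highest stress levels are converted" admits both readings:

* **Strength rule** (default in the pipeline): every intact element whose
  criterion exceeds a critical stress \(\sigma_c\) converts. Damage onset
  then occurs when the local stress concentration first reaches
  \(\sigma_c\) — which happens at different load levels for criteria of
  different magnitudes. This is what separates *aggressive* criteria
  (\(S_I, S_1, \sigma_{XX}\), the largest scalars) from the *inefficient*
  transverse shear \(\sigma_{YZ}\) (roughly fifteen times smaller on a
  tensile fiber), and it is the only rule of the two that produces a
  genuine onset stage: a fixed per-increment quota forces damage from the
  very first increment for every criterion, erasing the onset differences
  that the criterion comparison is about, and at desk scale it also
  severs the small cross-section within a few increments.
* **Fraction rule**: the fixed fraction `f` of the intact elements with
  the highest criterion values converts at each increment (ties broken
  toward the lower element index). This is kept as the
  `strength = NULL` mode for controlled criterion comparisons at constant
  load and for the ranking-oracle tests.

The default critical stress is \(\sigma_c = 200\) MPa. Reported tensile
strengths for hemp span roughly 280–1700 MPa at the fiber scale; with
stress-concentration factors of 2–4 at notch roots, lumen constrictions
and grip corners, a local element strength of 200 MPa puts nominal
failure in the low hundreds of MPa, the lower end of that scatter, and
lets all eight criteria reach onset within the applied ramp.

# Load schedule

The end displacement ramps from 0.1% to 8–10% nominal strain. The
function default is a linear ramp; the pipeline sweeps use logarithmic
spacing. The reason is resolution: criterion magnitudes span an order of
magnitude, so their onset windows sit at strains from ~0.2% to ~6%. A
linear ramp with a few dozen increments steps over the early windows in
one or two increments; log spacing gives every decade of strain the same
number of increments, resolving each criterion's onset-growth-saturation
curve within a single schedule. One solve per increment is performed (no
inner re-equilibration); an optional `innerResolve` loop re-solves at the
same load while the redistributed peak still grows.

A run stops early when the maximum criterion value over intact elements
falls below 1% of its first-increment value (the stress state has
collapsed — saturation), or when the intact elements no longer form a
face-connected path between the loading ends (the specimen has severed).

# What the synthetic generator emulates — and what it does not

The generator rasterizes an elliptical solid cross-section (equivalent
diameter `d`, major/minor ratio `shapeFactor`), extruded along X, with:

* **Lumen**: an elliptical tube spanning the full length, with area
  fraction `lumenFraction` and aspect `lumenAspect` (default 2). The
  tube's cross-section is modulated axially by a smoothed log-normal
  field (`lumenWaviness`, default 0.25 log-units, correlation one
  diameter), normalized so the realized porosity matches the requested
  fraction. The waviness is essential, not cosmetic: imaged lumina show
  mean cross-section areas several times their median — strong axial
  variation — and a perfectly straight tube parallel to the load
  concentrates no axial stress, whereas local widenings do. This is what
  lets the lumen act as the interior stress concentrator seen in the
  simulations.
* **Notches**: V (triangular prism; surface opening `w` along the axis,
  depth `h`) or U (semi-elliptical prism, semi-axes `w/2` and `h`),
  carved as solid-to-air conversion on one side of the fiber. The opening
  angle obeys \(\tan(\theta/2) = w/(2h)\).
* **Surface roughness**: a correlated Gaussian radial perturbation of the
  outer boundary with prescribed RMS amplitude and axial correlation
  length, clipped so the lumen wall is never breached and constrained to
  create no enclosed cavities. Rescaled desk fixtures can request a floor
  on the amplitude in voxel units, because sub-voxel roughness rasterizes
  to a smooth surface.

Four presets carry the descriptors of the four imaged specimens: `FXU4`
(U-notched bundle, d = 232 um, shape factor 3.23, porosity 9%), `FU`
(U-notched, d = 44 um, shape factor 1.28, porosity 4%), `FIV15`
(V-notched, d = 18 um, no lumen; notch 7.7 um by 2.8 um) and `FU19`
(U-notched, d = 23 um, no lumen, shape factor 1.78). Notch dimensions
for FXU4, FU and FU19 are not part of the printed descriptors; the preset
values sit inside the machined ranges (openings 4–108 um, relative depths
0.1–0.6 of the diameter).

What the generator does **not** emulate: cell-wall layering (S1/S2 walls,
middle lamellae), kink bands as a mechanical feature, partial-volume gray
levels, reconstruction artifacts, and multiple fibers per volume. Passing
tests on these synthetic stand-ins therefore demonstrate the pipeline's
internal consistency and its qualitative response to notch, lumen and
roughness geometry — not quantitative agreement with any particular real
fiber.

# Segmentation and morphometrics

Thresholding (Otsu by default) is followed by morphological opening and
closing with a Euclidean-ball structuring element (3D, 6-connectivity
throughout). The exterior air is flooded from the four *lateral* boundary
faces; the two X end faces are never seeds, because the fiber is cut
there and the open-ended lumen would otherwise be flooded as exterior
(corner-seeded flooding is available as a strict mode). Porosity is
internal air over internal air plus solid — a property of the fiber, not
of the field of view. Per-slice lumen and cross-section geometry come
from second-moment ellipse fits (with the 1/12 voxel-footprint
correction), areas from voxel counts.

# Numerical choices

* **Element**: trilinear hexahedron, 2x2x2 Gauss integration, VTK corner
  ordering. Units are um, MPa, uN (consistent).
* **Solver**: matrix-free Jacobi-preconditioned conjugate gradients on
  the Dirichlet-reduced system; the global operator is applied
  element-by-element with the shared unit-stiffness matrix scaled by each
  element's modulus. Default relative-residual tolerance 1e-8 with an
  iteration cap of \(10\sqrt{\mathrm{dof}}\); the damage sweeps use 1e-5
  and a fixed cap, since the per-increment top-of-ranking is insensitive
  to the last digits of the field. Warm starts scale the previous
  increment's solution by the displacement ratio, which makes pre-onset
  increments essentially free.
* **Ties** in the fraction rule break toward the lower element index;
  element order is the lexicographic voxel order, so results are exactly
  reproducible.
* **Degenerate inputs**: constant volumes require an explicit threshold;
  an all-zero damage curve yields explicit NA stage boundaries; slices
  with fewer than 5 lumen voxels are skipped and counted; identified
  Poisson ratios are clamped to (0, 0.5) with a warning.
* **Stage detection** uses 1%/99% of the final ratio (free choices — the
  stages are named in the literature but not thresholded), tolerates
  sub-2% non-monotonicity, and is invariant to rescaling of the ratio
  axis. Modality uses a moving-average smoothed growth rate and a
  25%-prominence two-peak rule.
* **Criterion categories** come from fixed-seed k-means (k = 3) on the
  standardized (onset increment, final ratio) plane: *aggressive* is the
  earliest-onset cluster, *inefficient* the latest-onset/lowest-ratio
  cluster among the rest. The three groups are narrative in the
  literature; this clustering rule is this package's own quantitative
  rendering.

# Desk-scale study conditions

Full-resolution meshes of this kind reach tens to hundreds of millions of
degrees of freedom; this package targets a single CPU, so the shipped
tests and the acceptance script run rescaled fixtures: fiber diameters of
12–32 voxels, lengths of 2–3 diameters, 40–48 load increments, meshes of
roughly 2,000–6,000 elements (10,000–25,000 dof). Geometry ratios
(shape factor, porosity, relative notch size) are preserved by rescaling
the voxel size. The bundle sweep ramps to 8% nominal strain; the
identification examples use 1% strain bars. At this scale the grip
regions occupy a far larger volume fraction than in a real gage (which is
tens of diameters long), which inflates the damage totals of the
longitudinal shear criteria — the transverse-shear criterion and the
group means still rank as expected, but the per-criterion ordering
between \(|\sigma_{XY}|\) and the principal-stress group is not reliable
at this scale. Fixture seeds are fixed in the test suite: they are part
of the study conditions, like any other fixture parameter.

# Identification of the elastic constants

The model is strictly linear in \(E_0\), so one trial simulation
identifies the modulus from a measured force-displacement slope:
\(E_0 = E_{\mathrm{trial}} \cdot s_{\mathrm{exp}} / s_{\mathrm{model}}\),
exact to solver precision. The Poisson ratio uses the same one-step
linear correction on the mean mid-span lateral contraction; contraction
is only approximately linear in \(\nu\) under glued-end conditions, so
the recovery is accurate to about \(\pm 0.02\) rather than exact — the
documented tolerance reflects the approximation, not noise.

# Known limitations

* Linear isotropic elasticity with binary phase contrast; no gray-level
  graded moduli, no cell-wall anisotropy or inelasticity.
* Element-level degradation only: no crack-tip fields, no fracture
  toughness, no cohesive zones.
* The critical stress \(\sigma_c\), the roughness statistics and the
  lumen waviness are free parameters of the synthetic conditions; none is
  measured from data.
* Desk-scale fixtures distort grip-dominated quantities (see above), and
  strict two-peak bimodality of the growth rate is not stable at these
  mesh sizes — the localized-to-diffuse transition is measured instead as
  a late-growth versus early-growth rate ratio.
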