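---
title: "Corneal layer profiles and keratoconus screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal layer profiles and keratoconus screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcOCT)
```

# The problem

Sub-clinical keratoconus — the still-asymptomatic fellow eye of a patient
with unilateral keratoconus, with normal topography — is the population
that matters most for refractive-surgery screening, and the hardest to
detect.  Ultra-high-resolution OCT resolves the corneal epithelium and
Bowman's layer individually, and both remodel early in the disease: the
epithelium thins focally over the incipient cone, Bowman's layer thins
inferiorly.  kcOCT implements the full measurement-to-decision chain that
turns vertical-meridian B-scans into a screening decision:

1. **Segmentation** of the four interfaces (air–epithelium,
   epithelium–Bowman, Bowman–stroma, stroma–posterior) by a
   gradient-cost shortest-path search.
2. **Refraction correction** of the sub-surface geometry by Snell
   ray tracing with a corneal group index of 1.389.
3. **Thickness profiling**: perpendicular-to-surface thickness, 10-zone
   averaging of a 1,000-A-scan window per region, and co-registration of
   the central, superior and inferior regions at the Bowman's-layer
   edges into one ~11-mm vertical profile per layer.
4. **Twelve diagnostic indices** per eye (EEI, BEI, SEI, their `_MAX`
   variants, EPV/BPV/SPV, EPSD/BPSD/SPSD).
5. **Group statistics**: one-way ANOVA, forward Wilks-λ stepwise linear
   discriminant analysis with F-to-enter 3.84, and empirical ROC
   analysis with Youden cutoffs.

Because no clinical images ship with the package, a first-class
synthetic-cornea module generates ground-truth layered geometry,
rendered B-scans and whole cohorts; every stage of the pipeline is
validated against that ground truth.

# Scan geometry

The reference geometry is a 1365 × 2048-pixel B-scan covering 2.02 mm of
depth *in air* and 8.66 mm of width.  Two consequences are used
throughout:

* the lateral pitch is 8.66/2048 mm per A-scan, so 100 A-scans span a
  0.42-mm chord and the 1,000-A-scan analysis window spans 4.23 mm;
* one axial pixel is ~1.48 µm of optical path in air, i.e. ~1.06 µm of
  tissue after division by the refractive index — which is why sub-pixel
  boundary refinement matters for micrometre-level thickness.

The analysis window is defined *physically* (the 4.23-mm chord), so
down-sampled geometries — used for fast simulation — keep identical
zonal arithmetic.

```{r geometry}
g <- scanGeometry()
c(window_mm = round(windowChord(g), 2), zone_mm = round(zoneChord(g), 2))
round(zoneChordBounds(3:5), 2)   # zone bounds counted outward from the apex
```

# Segmentation

The boundary search is an exact dynamic program: for a cost grid
`c(r, col)` it returns the left-to-right row path minimising total cost
under a bounded per-column row change (`max_step`, default 2 px).  The
cost is `max(g) − g + 1e-6` where `g` is the polarity-matched signed
vertical gradient (central differences): strictly positive, so path
length is well defined, and monotone in the gradient, so the optimum
maximises accumulated edge contrast.  Ties between transitions prefer
the smaller row change, then the upper row — outputs are deterministic
and column-order invariant.  The optimality of the dynamic program is
tested against exhaustive path enumeration on small grids.

Design choices worth knowing:

* **Band searches.** The air–epithelium surface is found unconstrained;
  each deeper interface is searched in a band anchored to the interface
  above it (nominal epithelial/Bowman thicknesses of 50 µm and 17 µm,
  band half-width 10 px or ~20 µm, whichever is larger).  The lower edge
  of the epithelium–Bowman band stays ≥3 px clear of the much stronger
  surface edge, otherwise the path would lock onto it.
* **Seeded Bowman–stroma search.** The Bowman–stroma interface has the
  weakest contrast in clinical images; when 5–6 manually clicked seed
  points are supplied they are interpolated by a natural cubic spline
  (linear extrapolation beyond the outer seeds) and the path is searched
  within ±10 px of that initialisation.  A correction hook overwrites
  stated columns of any trace after the fact; ordering violations are
  clipped and the columns flagged.
* **Sub-pixel refinement.** A parabola through the cost at the three
  rows around the path gives the vertex position.  For a partial-volume
  (area-weighted) edge this recovers the exact sub-pixel boundary, which
  is also how the renderer draws edges — so the noiseless round trip is
  exact to well below 0.1 px.
* **Validity by contrast.** A trace is marked invalid wherever the
  polarity-matched gradient under it falls below 30 % of the trace's
  maximum.  This is what terminates the Bowman traces at the layer's
  peripheral edge, and it also flags far-peripheral columns where the
  interface slope exceeds `max_step` rows per column (outside the
  analysis windows with the default geometry).
* **Posterior surface.** Stromal thickness needs the posterior boundary;
  it is found with the same bright-to-dark machinery well below the
  Bowman–stroma trace.  Columns where the posterior leaves the frame are
  invalid.

# Refraction correction and thickness

Above the anterior surface light travels in air, so the surface trace
maps directly to physical coordinates.  Below it, each A-scan's ray is
refracted once at the surface: the incidence angle comes from the local
surface tangent (smoothed finite difference over ±25 A-scans at the
reference sampling), the transmitted direction from Snell's law with
n₁ = 1 and n₂ = 1.389, and the optical path below the surface is divided
by n₂ and laid along the refracted ray.  A single index and a single
refraction are used for all layers; refraction at internal interfaces is
neglected (the index steps between corneal layers are far smaller than
the air–tissue step).  Setting the index to 1 makes the correction the
identity exactly, and a 45° incidence refracts to
`asin(sin 45°/1.389) ≈ 30.6°` — both are tested as closed forms.

Layer thickness is measured from the layer's upper interface point along
the local inward normal of the *anterior* surface to the interpolated
lower interface, in micrometres.  This is exact for the synthetic
ground truth, whose interfaces are stacked along the anterior normals.
Columns whose normal does not meet the lower trace in the scan are
invalid.

# Zonal profiles and registration

For the central region the 1,000-A-scan window is centred on the apex
(the A-scan of maximal corrected surface elevation); for the peripheral
regions it runs from the in-view Bowman's-layer edge toward the corneal
centre.  Each tenth of the window is averaged into a zone, zones ordered
inferior → superior; invalid A-scans are excluded from their block mean,
and zones with under 60 % valid A-scans are flagged partial and excluded
downstream, so a handful of pixels can never define a zonal minimum.
Bowman edges are the termini of the longest valid run of the
Bowman–stroma trace, closing gaps of up to 5 columns so single-column
dropouts do not split the run.

The three regions are merged on a fixed chord axis anchored at the apex
with bin *edges* at multiples of the zone chord (0.423 mm): bin *j*
covers `[j·w, (j+1)·w)`.  With edge-anchored bins the central region's
10 zones coincide exactly with bins −5…4, and the inferior/superior
halves of the profile are disjoint without excluding any bin — the
halves are exactly the zones-1–5 / zones-6–10 split of the zonal
numbering.  Peripheral regions are anchored at their Bowman edge,
`semi_span_bins` (default 13, ≈5.5 mm) bins from the apex; the default
synthetic cornea has an 11-mm edge-to-edge meridian, so the merged
profile spans 26 bins and overlapping bins (two per side) are averaged
with equal region weights.  A gap of one bin between windows is bridged
by interpolation and flagged invalid; larger gaps are an error.

Two representational caveats are deliberate:

* The edge-to-apex distance cannot be read off any single scan, so
  peripheral anchoring assumes the canonical semi-span unless told
  otherwise.  Zones are labelled both by signed bin index and by
  distance from the apex, because the two conventions (inferior→superior
  numbering vs. distance-from-centre naming) coexist in practice.
* Zone chords are measured in each scan's own frame.  For rotated-gaze
  peripheral scans chord and arc position differ by up to ~1 % at the
  window ends, which displaces peripheral zones by a few hundredths of
  a millimetre on the common axis.  This is negligible for the thin
  layers, and worth ~1 µm for the steep peripheral stromal gradient —
  the same overlap imprecision the imaging protocol itself accepts.
  The registration round-trip test therefore checks losslessness on
  exactly-anchored zonal samples, and the rendered-pipeline tests check
  thickness fidelity per A-scan.

# The twelve indices

For each layer's merged profile, with the inferior half `I` (bins below
the apex) and superior half `S` (bins above):

| Index | Definition | Unit |
|---|---|---|
| EI (EEI/BEI/SEI) | `100 · min(I) / mean(S)` | % |
| EI_MAX | `100 · min(I) / max(S)` | % |
| PV (EPV/BPV/SPV) | RMS of valid bins about the profile's own mean | µm |
| PSD (EPSD/BPSD/SPSD) | RMS of valid bins about the normal-cohort pattern average | µm |

`EI_MAX ≤ EI` always (mean ≤ max), with equality only for a constant
superior half; EI and EI_MAX are scale-invariant while PV scales
linearly — both properties are tested.  The pattern average is the
per-bin mean of a reference cohort of normal eyes, and PSD uses only
bins valid in both profile and pattern since peripheral extent varies
by eye.  Indices are computed in full precision and rounded only in
reports.

# Group statistics

* **ANOVA**: fixed-effects one-way ANOVA per variable via `stats::aov`,
  with group means, SDs and 95 % CIs; optional Dunnett-style post-hoc
  contrasts of each patient group against normal (via multcomp).  No
  multiple-testing correction is applied across zones or indices by
  default, matching common practice in this literature; a Bonferroni
  adjustment can be applied by the caller.
* **Stepwise LDA**: forward-only Wilks-λ selection.  At each step the
  candidate minimising λ of the enlarged set enters if its partial
  F-to-enter exceeds 3.84 (the asymptotic 5 % point of F with one
  numerator df); there is no removal step, because only an entry rule is
  standard for this procedure.  λ-ties break lexicographically, so the
  fit is invariant to column order.  The discriminant function on the
  selected set is Fisher's two-group solution (or the leading canonical
  variate for three groups), scaled to unit pooled within-group variance,
  centred at the grand mean and oriented so diseased eyes score higher.
  The construction contrast defaults to all supplied groups; a
  restricted feature set (e.g. only EEI_MAX and BEI_MAX) can be fitted
  by subsetting the feature columns.
* **ROC**: empirical curve over all distinct thresholds; AUC by the
  trapezoidal rule, which equals the Mann–Whitney concordance
  probability with ties counted ½ (tested by pair enumeration, and
  cross-checked against pROC).  The reported cutoff maximises Youden's
  J = sensitivity + specificity − 1, ties broken toward higher
  sensitivity; Youden is used because a single cutoff criterion has to
  be chosen and it is the standard default.  Ectasia indices count as
  positive *below* the cutoff, variation/deviation indices *above*.

# The synthetic-cornea generator

The generator defines the study conditions; its defaults are not tuning
knobs.  Per group (normal, sub-clinical KC, KC) and layer it draws

```
thickness(s) = baseline(s) + subject_offset − depth · exp(−(s − c)² / (2σ²))
```

with `s` the signed meridian position (negative inferior) and:

* **Regional anchors.** Baselines are natural splines through three
  regional anchor values (inferior/central/superior window means), with
  the anchors *solved* so the regional 4.23-mm window means match the
  published group means after the expected cone thinning is subtracted —
  the window mean is linear in the anchors, so this is a 3×3 system.
  Normal central epithelium is 53.48 µm, Bowman ~17 µm, stroma shows the
  physiological thin-centre "doughnut" (460 µm centre vs ~530 µm
  periphery).
* **Cone.** A Gaussian in meridian position — the simplest shape with
  two interpretable parameters that matches "localized thinning".  Its
  centre is drawn uniformly in [−2.5, 0] mm (central-to-inferior, where
  ectatic thinning concentrates), σ = 1 mm.  Depths per layer are set
  first-order from the published ectasia-index group means (the EI drop
  below normal times the superior-half thickness): ~5/3.5/8 µm for
  sub-clinical eyes and ~13/5/65 µm for manifest keratoconus, with zero
  cones for normals.  Group-mean zonal tables alone would understate
  these depths because cone positions vary between eyes and average out.
* **Variability.** One additive offset per layer per eye (SD = the
  published regional SDs, ~2.8 µm epithelium, ~1.5 µm Bowman, ~30 µm
  stroma) plus independent per-zone noise calibrated to inter-grader
  repeatability (1.4/1.25/4 µm).  Spatial correlation of thickness
  beyond the common offset is *not* modelled — nothing quantitative is
  published to calibrate it — so passing tests demonstrate pipeline
  correctness, not that real corneas are this well behaved.
* **Geometry and rendering.** The anterior surface is a circular arc
  (radius 7.74 mm for normals, 6.58 mm for keratoconus, from average
  keratometry); aspheric terms are out of scope.  Bowman's layer
  terminates 13 zone-chords (~5.5 mm) of arc from the apex on each side,
  tapering over 0.05 mm.  Peripheral scans are rendered with the gaze
  rotation that brings the respective edge ~2.16 mm inside the field of
  view.  Rendering assigns each tissue a fixed mean intensity
  (background 0.05, epithelium 0.55, Bowman 0.80, stroma 0.45), blends
  boundary pixels by partial volume, places sub-surface interfaces at
  their *optical* depth (geometric distance × 1.389 along the refracted
  ray), adds Gaussian intensity noise (SD 0.02 by default) and quantises
  to 8-bit levels.  Speckle physics, motion artifacts and 3-D scanning
  are not emulated.

What the defaults reproduce, by construction: the ordering of central
epithelial thickness across groups, the localized inferior/central
thinning patterns, ectasia-index group means close to the published
ones, and — emergently — the near-identity of stromal indices between
sub-clinical and normal eyes (diffuse stromal differences cancel in the
within-eye EI ratios), which is exactly why epithelial indices dominate
stromal ones for sub-clinical detection.

# Numerical choices and degenerate inputs

* Cost ε = 10⁻⁶ keeps path costs strictly positive without disturbing
  the argmin; the parabolic vertex falls back to the integer row when
  the curvature is below 10⁻¹².
* The DP feasibility of a search band under `max_step` is checked up
  front; an empty or unreachable band is an error, not a silent clamp.
* Thickness intersection uses a fixed-point iteration (≤12 steps,
  10⁻⁹ mm tolerance); non-convergent or out-of-range columns are marked
  invalid rather than extrapolated.
* A featureless image (no detectable surface), a peripheral scan whose
  Bowman edge is out of view, a window truncated by the image border,
  single-class ROC input, and a singular pooled covariance all raise
  errors naming the offending quantity.
* Rendering draws all randomness from an explicit seed through a
  private RNG stream that is restored afterwards; cohort seeds derive
  from one master seed, so every artefact is reproducible from
  `(config, seed)`.

# Problem sizes used in validation

The test-suite simulations are sized to be decisive yet quick: rendered
recovery tests use half-scale scans (342 × 512 px — identical physical
extents and zonal arithmetic), cohorts of 5–15 rendered eyes and 20
eyes per group for the profile-level study; the Monte-Carlo recovery of
the central epithelial mean uses 400 draws.  The acceptance script
re-runs the rendered recovery on a 15-eye cohort and the diagnostic
study at 20 eyes per group.

# Known limitations

* Only the vertical meridian is modelled and analysed; no maps.
* Fully automatic Bowman–stroma segmentation on low-contrast clinical
  images is out of scope; the seeded spline + banded search mirrors the
  semi-automatic protocol.
* The posterior-surface search is a pragmatic extension (the stromal
  indices need it); clinical posterior segmentation is harder than the
  synthetic case exercises.
* Peripheral chord-vs-arc registration imprecision (~1 µm for the
  stroma at the profile ends) is inherent to edge-anchored chords.
* The generator's between-eye model (offset + independent zone noise)
  is a stand-in for unquantified spatial correlation; discriminant
  performance on synthetic cohorts should be read as a qualitative,
  not clinical, statement.
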