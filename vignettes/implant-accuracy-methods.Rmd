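---
title: "Measuring guided implant placement accuracy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring guided implant placement accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantdev)
```

## The measurement problem

When dental implants are placed through a 3D-printed surgical template, the
clinically relevant question is how far each placed implant ended up from its
virtually planned position. Both positions are reduced to a pose: the 3D
coordinates of the implant shoulder (the coronal platform centre) and apex,
which together define the longitudinal axis. With the planned shoulder at
point A and the placed shoulder at point B, four deviations are measured at
the implant shoulder:

* **Global deviation** `|A - B|`: the 3D distance between the shoulder
  centres.
* **Angular deviation** α: the angle between the two longitudinal axes,
  computed as `atan2(|u × v|, u · v)` — numerically stable where the
  arc-cosine formulation loses precision near 0° and 180°.
* **Lateral deviation** `|A - C|`: point C is where the *placed* axis pierces
  the plane through A perpendicular to the *planned* axis. This is a true
  line–plane intersection, not a projection of B onto that plane; the two
  differ whenever the axes diverge.
* **Depth deviation** `|A - D|`: point D is the foot of B on the planned
  axis, i.e. the component of the shoulder displacement along the planned
  axis. The signed value (positive = apical) is retained in every record;
  tables print the magnitude, following the convention of published accuracy
  tables.

Two degenerate cases are handled explicitly rather than silently. If the
placed axis lies in the shoulder plane (direction cosine below 1e-6), point C
is not unique and the lateral deviation is recorded as missing — for that
metric only. Axes are oriented shoulder→apex and the angle is *not* folded to
[0°, 90°]: a flipped implant reads near 180° and triggers a warning, because
folding would disguise a gross orientation error as a small one.

All metrics are invariant under a common rigid motion of both poses (the
tests verify this to 1e-9 over random transforms), so the choice of world
frame is immaterial *once both poses are expressed in it*. The pipeline order
is therefore: fit analogue poses on the post-operative data, register the
post-operative dataset into the planning frame, then measure.

## Registration

Two alignment steps precede measurement.

**Known correspondence (Kabsch/Umeyama).** `closed_form_align()` solves the
least-squares proper rigid transform between paired point sets via SVD of the
cross-covariance with reflection correction. It is exact on noiseless
correspondences and globally optimal for the correspondence given.

**Unknown correspondence (trimmed ICP).** Surface scans of the same anatomy
have no point-to-point pairing, and segmentations of titanium implants are
contaminated by metal-artifact scatter. `iterative_surface_align()` alternates
exact nearest-neighbour matching with closed-form updates, keeping only the
`(1 - trim_fraction)` closest pairs per iteration. The trimmed RMSD sequence
is provably non-increasing (each step can only improve the trimmed
objective), which the tests assert; non-convergence within `max_iter` is
reported as a flag, not an error. The default `trim_fraction = 0.2` reflects
typical scatter contamination; `0` disables trimming. Nearest neighbours are
exact (brute force, chunked), so results are deterministic — spatial indexing
would be an internal optimisation, never a behavioural change. The default
start is the identity, adequate for pre/post scans of the same patient that
are already roughly in the same frame; a centroid-plus-principal-axes seeding
is available for larger initial misalignments.

**Analogue pose fitting.** `fit_analogue_pose()` estimates an implant pose
from its segmented surface cloud. The axis starts at the dominant principal
direction of the centred cloud and is then refined by a cylinder fit that
minimises the variance of radial point distances over the mid-shaft (the
middle 70% of the axial extent, mask fixed from the initial axis). The
refinement matters: on a finite random sampling of a 1.75 × 13 mm cylinder,
PCA alone leaves a tilt of a few tenths of a degree, while the refined axis
is exact on noiseless clouds. The shoulder is located on the fitted axis at
the coronal cap. Within the coronal 10% slab, cap points are separated from
side-wall points by radial distance (below 0.8 of the radius estimated from
the mid-shaft); the shoulder is their mean axial position. Using the raw slab
centroid instead would mix cap and wall points and bias the shoulder several
tenths of a millimetre into the implant, which is why the cap points are
isolated first; when fewer than 10 cap points exist (sparse clouds) the slab
centroid is the fallback. Axial orientation is inherently ambiguous for a
near-cylinder, so without an `apex_hint` the pose is returned with an
explicit ambiguity flag rather than a silent guess. Clouds whose first two
principal extents differ by less than a factor 1.5 are rejected as unfittable.

## Agreement statistics

`describe()` reports mean and SD. The SD divisor defaults to the population
form (divisor *n*): recomputing the packaged cohort table's footer from its
per-implant values reproduces the printed SD only with divisor *n*
(3.38 vs 3.46 with *n* − 1 against the printed 3.39 for the angular column),
so that form is the default and the sample form is an explicit option.

`icc_absolute_single()` implements the intraclass correlation for
inter-observer reliability: two-way model, absolute agreement, single
measures — ICC(A,1) in McGraw–Wong notation, the statistic quoted when two
observers independently re-measure a sample of implants. From the two-way
ANOVA mean squares (rows = subjects, columns = observers),

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with confidence bounds from the standard F-quantile construction with
Satterthwaite degrees of freedom. The point estimate is identical under the
two-way random and two-way mixed models, so the distinction in published
methods sections does not affect the number. The implementation is validated
two ways: against a from-definitions ANOVA oracle (`stats::aov`) to 1e-9 on
random matrices, and against an independent Python implementation (pingouin)
on a frozen matrix. Perfect agreement (duplicated columns) returns exactly
1.0 with a degenerate interval. The raw two-observer measurements behind
published ICC values are generally unpublished, so the machinery — not any
specific published coefficient — is what is validated here.

`summarise_cohort()` applies per-metric listwise exclusion: an implant with
only an undefined lateral deviation leaves the other three summaries, and a
fully missing implant (e.g. a template that did not fit, so accuracy was
never measured) leaves all four. Each summary row carries its own `n`.

## The synthetic cohort generator

No deposited clinical coordinates exist for this kind of study, so the
package ships a generator that emulates the study design well enough to
exercise every pipeline stage. It models:

1. **Template seating error** (per patient, shared by all implants): a
   rotation of angle |N(0, σ_seat)| about a random *horizontal* axis through
   the nasal-aperture fulcrum — the template's brackets seat on the pyriform
   rim, so seating errors pivot there — composed with a N(0, σ_trans)
   translation per component. A fully random rotation axis is available by
   option.
2. **Drill-sleeve wobble** (per implant): a tilt of |N(0, σ_sleeve)| at
   uniform azimuth about the implant shoulder.
3. **Unguided insertion depth** (per implant): a N(0, σ_depth) slide along
   the drilled axis — in a semi-guided protocol the template constrains the
   osteotomy but the insertion depth is freehand.
4. **Observer noise** (per observer, for ICC fixtures): independent shoulder
   and axis perturbations, after which the deviation metric is recomputed.

Planned poses sit evenly on a circular anterior arch (radius 25 mm) with
axes tilted up to 10° from vertical and lengths drawn from the 13/15 mm
sizes used clinically. The arch is schematic on purpose: only the error
geometry matters for testing the metrics, so no anatomical mesh is modelled.
Draws are consumed in a fixed documented order (per patient: planned
tilts/azimuths/lengths → seating → per implant: sleeve tilt, azimuth,
depth), making cohorts bit-reproducible from the seed.

Defaults (σ_seat = 2°, σ_trans = 0.3 mm, σ_sleeve = 6°, σ_depth = 0.5 mm)
were chosen once from error-propagation arithmetic so that default cohorts
land in the range reported for guided surgery in the atrophic maxilla (mean
angular deviation a few degrees, mean global deviation around 1 mm); the
packaged 500-patient run gives means of about 5.0° and 0.93 mm. They are
calibration choices, not estimates from any dataset: published studies do
not decompose their error budgets quantitatively.

The generator supports sharp distributional checks. With a single active
error source the corresponding deviation is exactly half-normal, with mean
σ·√(2/π); the tests verify this within three standard errors at 10,000
implants. With every σ at zero the truth records are identically zero.
`lever_arm_check()` isolates the seating-rotation geometry: mean lateral
deviation grows linearly with fulcrum distance (≈ d·E|θ| in the small-angle
regime, verified within 5% at σ = 1°), which is the quantitative version of
the argument for bracing a template on the nasal aperture close to the
implant sites.

What passing these tests does *not* show: real CBCT segmentations are not
ideal cylinders, bone-density variation couples the error sources, and a
badly fitting template is a categorical failure, not a Gaussian one. The
simulator validates the measurement machinery, not clinical accuracy claims.

## Numerical choices

* Geometric identity assertions at 1e-9; near-parallel/perpendicular guards
  at 1e-6 (double precision at millimetre scale).
* The report writer is the only place values are rounded (1 decimal per
  implant; footer mean (SD) with the angular column at 2 decimals); every
  internal pipeline carries full precision.
* Implant clouds store scatter outliers by replacing exactly
  `round(fraction × n)` points, so outlier counts are testable.
* ICP keeps at least 3 pairs regardless of trimming, and `closed_form_align`
  rejects collinear configurations (second singular value ≤ 1e-9 relative).
* Problem sizes in the test suite — 1,000 oracle pose pairs, 10,000-implant
  calibration cohorts, 1,500–2,000-point clouds — were chosen as the
  smallest sizes at which Monte-Carlo bounds are sharp.

## Known limitations

* The surface-matching algorithms of commercial planning suites are
  unpublished; trimmed ICP satisfies the same contract (rigid, robust,
  convergent) but equivalence with any proprietary implementation cannot be
  tested.
* Depth sign conventions vary between studies; here positive is apical, and
  printed tables show magnitudes.
* The fixture table stores deviations only — no coordinates are published —
  so it exercises the statistics and reporting path; the geometry path is
  exercised by simulation.
* No mesio-distal/bucco-lingual decomposition is offered: defining those
  planes requires human interpretation, and the deviation construction used
  here avoids it deliberately.
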