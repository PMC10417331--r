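---
title: "Landmark-based planning of the hip center of rotation: methods and design notes"
author: "hipplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based planning of the hip center of rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipplan)
```

## The problem

In revision hip arthroplasty the acetabulum is often so damaged (Paprosky
II–III defects, cup migration beyond 3 cm) that the native center of
rotation (COR) cannot be located on the diseased side. The workflow this
package implements transfers the COR from the *contralateral intact* hip:
three anatomical reference planes are built from six bony landmarks, the
intact femoral head is fit with a sphere, and its center is mirrored across
the sagittal plane. The planned revision cup is then parameterized by
radiographic inclination and anteversion around that mirrored COR, and
planned-versus-achieved agreement is quantified after surgery.

All coordinates are RAS millimetres (x toward patient right, y anterior,
z superior). LPS input — the default of common segmentation exports — is
negated in x and y at the file boundary; one internal convention prevents
sign bugs, and the conversion is its own inverse.

## The pelvic frame and its underdetermination

The clinical construction names only two landmarks per plane: sagittal
through the pubic symphysis and sacrum centers, axial between the ischial
tuberosity tips, coronal between the ischial spine tips. Two points do not
fix a plane, so a completion rule is needed. We chose Gram–Schmidt
orthogonalization in the order sagittal → axial → coronal:

1. midline direction m̂ = unit(sacrum − symphysis);
2. x̂ = unit of the tuberosity chord orthogonalized against m̂ — the
   sagittal normal. The sagittal plane therefore contains *both* midline
   landmarks exactly;
3. ẑ = unit of (spine midpoint − tuberosity midpoint) orthogonalized
   against x̂ — the axial normal;
4. ŷ = ẑ × x̂, giving a right-handed triad.

This rule is deterministic, exact on mirror-symmetric pelves (a perfectly
symmetric landmark set yields the symmetry plane as sagittal plane and zero
residual tilts), and equivariant under rigid motion. Its cost is that the
axial and coronal planes contain their defining landmark pairs only
approximately on asymmetric anatomy. The residual tilt of each defining
chord out of its plane is reported in degrees as `quality`, and a warning is
raised above 5° — on real pelves tilts are typically a degree or two; values
above 5° indicate mislabelled or badly placed landmarks rather than
anatomy.

The frame origin for reporting is the pubic symphysis center; for plane
distances any on-plane anchor is equivalent.

Axis-distance bookkeeping: the published cohort tables label COR positions
as X/Y/Z-axis distances with inconsistent plane attributions. This package
defines them unambiguously as the signed distances to the sagittal (x),
coronal (y) and axial (z) planes, in that order, and makes no further
attempt to guess the original labelling.

## Sphere fit and mirroring

The manual step of "drawing a sphere on the femoral head" is replaced by a
least-squares fit to clicked or synthetic head-surface points: a Kåsa-style
algebraic solve for initialization, then Gauss–Newton on the orthogonal
residuals |pᵢ − c| − R to a step tolerance of 1e-10 mm or 100 iterations.
The fit is exact on noiseless spherical data and needs ≥ 4 non-coplanar
points (coplanarity is detected by the smallest singular value of the
centered cloud). A manually determined center can still be supplied via
`plan_cor(..., intact_cor =, head_radius =)`. Whether the fitted radius
represents the native or a prosthetic head on the intact side is left to
the user; the fit just reports it.

Mirroring is implemented as reflection across the constructed sagittal
plane rather than copying distance coordinates. Given the orthonormal
frame the two are mathematically identical — the planned-minus-intact
distance triple is (−2·d_sagittal, 0, 0) — but the reflection is exact by
construction and testable as an involution and isometry.

## Cup pose convention

The planning statement "the axial plane determines inclination, the coronal
plane anteversion" reverses common radiographic usage; rather than guess
the intended convention we fixed the **radiographic** definition:
anteversion is the angle between the cup axis and the coronal plane
(RA = asin(axis·ŷ)), inclination the angle of the axis's coronal-plane
projection from the inferior direction (RI = atan2(axis·l̂, −axis·ẑ), with
l̂ the operated side's lateral direction). `axis_from_angles()` /
`angles_from_axis()` are exact inverses on RI ∈ [0°, 90°), RA ∈ (−90°, 90°);
a pure-anterior axis leaves RI indeterminate and is flagged. The
`convention` field on `cup_pose` exists so anatomical/operative definitions
could be added without breaking stored plans. Angles outside the customary
planning windows RI 30–45°, RA 10–20° warn but do not error — they are
clinical choices, not mathematical limits.

Cup geometry is a generic hemispherical shell based on the general shape
and dimensions of commercial revision systems (catalog 50–64 mm in 2 mm
steps, default 3 mm wall), not a replica of any proprietary implant.
Screw purchase is measured to the *last* ray–mesh exit (total bony
purchase, matching how surgical screw lengths are chosen);
`first_exit = TRUE` selects the more conservative first-exit length.

## Statistics

Paired *t*, Pearson *r* and the one-sample Kolmogorov–Smirnov statistic are
thin wrappers over the corresponding base-R tests, with two policy
decisions:

- identical paired vectors return t = 0, p = 1 (a perfect plan/outcome match
  is a result, not an error), while a *constant nonzero* difference —
  zero variance with nonzero mean — raises a degenerate-test error from
  `paired_t()` itself; cohort-level reports catch it and show the mean
  difference with an undefined t instead.
- the KS reference mean and SD are taken as supplied. If they were
  estimated from the same sample (the Lilliefors situation) the p-value is
  only approximate and the result carries a note saying so.

Accuracy records keep difference (measured − reference, mm) and percent
(100·measured/reference) mutually consistent at full precision; rounding to
two decimals happens only at presentation. Summaries use the sample SD
(n − 1). Published tables sometimes print unsigned difference magnitudes;
`records_from_difference_percent()` reconstructs the sign as negative
wherever percent < 100, the only reading consistent with the definition,
and back-solves reference = difference/(percent/100 − 1). The shipped
ten-case cohort table reproduces its published summary row exactly under
this rule.

## The synthetic pelvis

The generator emulates the planning inputs, not pelvic anatomy. Defaults
(chosen once, as plausible adult dimensions consistent with the cohort's
planned cup positions): tuberosity tips 120 mm apart, spines 90 mm apart
and 60 mm superior, 130 mm symphysis–sacrum midline span, ground-truth COR
at plane distances (86, 71, 52) mm, head radius 24 mm (a 54 mm cup), 200
head-surface points on a 120° cap (more than a hemisphere). Noise is
isotropic i.i.d. Gaussian per coordinate on landmarks and head points;
asymmetry is a rigid translation of the revision-side tuberosity/spine.
All generators are pure functions of (config, seed).

The hemipelvis mesh is deliberately schematic: a watertight star-shaped
surface around the revision COR whose boundary sits at the head radius
inside a 60°-half-angle recess cone (the articular surface) and at 60 mm
outside it, with a 20° cosine blend. Defects displace the recess region by
`migration` mm superiorly plus half that medially (`up_and_in`) or
laterally (`up_and_out`), and emit two edge landmarks spanning the
displacement so `measure_defect_length()` reproduces the caliper
measurement exactly.

What passing tests therefore show: correctness of the geometry, of the
mirror transfer, and of the statistics on controlled ground truth. What
they do not show: robustness to real segmentation artifacts, anatomical
asymmetry beyond rigid translation, metal artifacts in post-op CT, or
landmark placement variability between operators — the synthetic noise
model is isotropic and the pelvis is mirror-symmetric by construction.

## Numerical choices

- Unit-vector and orthogonality tolerances 1e-9; degenerate configurations
  (coincident landmark pairs, chords collinear with the midline) error
  rather than produce an arbitrary frame.
- Sphere fit: Gauss–Newton step tolerance 1e-10 mm, 100-iteration cap.
- Ray–triangle tests use Möller–Trumbore with barycentric tolerance 1e-9;
  intersections at t ≤ 1e-9 (the entry point itself) are discarded.
- STL vertices are merged on exact equality after parsing; degenerate
  (zero-area) triangles are dropped as load cleanup. Binary STL stores
  float32, so round-trips are exact to ~1e-5 mm at pelvic scales; units
  are assumed mm with no autodetection.
- Under 1 mm landmark noise the median planned-COR error over 200 seeded
  replicates is below 4 mm (an error amplification of roughly 3× driven by
  frame-normal rotation at an ~130 mm lever arm), and the median error
  grows monotonically over noise 0–2 mm; both are asserted in the suite.

Problem sizes in the test suite are kept small but representative: 200-point
head clouds, 60–200 replicate noise studies, meshes at 3–15° angular
resolution, 1000-seed statistics cross-checks at n ≤ 10.

## Known limitations

- No automatic landmark detection; landmarks come from segmentation
  software exports. Anterior-pelvic-plane (ASIS-based) frames are not
  implemented.
- COR estimation from the diseased side (Harris fossa, transverse-ligament
  methods) is out of scope; the method requires an intact contralateral
  hip.
- Achieved post-op poses are accepted as input; the package does not
  extract them from (metal-artifacted) post-op CT.
- Mesh handling is limited to triangle soups: no repair beyond
  degenerate-triangle removal, no booleans, no DICOM.
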