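---
title: "Methods: dural sac volumetry and its diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dural sac volumetry and its diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duravol)
```

## The problem

Dural ectasia — expansion of the dural sac with erosion of the adjacent
vertebral bodies, typically lumbosacral — is one of the systemic criteria
for Marfan syndrome (MFS). The established clinical quantification is
two-dimensional: the anteroposterior (AP) dural sac diameter divided by the
AP vertebral body diameter at the same level (the dural sac diameter ratio,
DSDR). A volumetric alternative divides the dural sac *segment volume* at a
level by the vertebral body volume at that level (the dural sac volume
ratio, DSVR). `duravol` implements the measurement geometry for the
volumetric approach on 3D label volumes, the derived indices, and the
diagnostic-accuracy machinery used to compare the two families of indices,
together with fully synthetic data sources (a 3D phantom and a parametric
cohort simulator) so every stage is testable end to end without patient
data.

Level conventions: dural segment volumes and DSVR exist for L3, L4, L5 and
S1; diameters and DSDR for L1–S1. The S1 vertebral body is not measured
volumetrically, so by convention `dsvr_S1` divides the S1 dural segment
volume by the **L5** vertebral body volume. S1 scalloping is the mean of the
S1 upper- and lower-endplate AP diameters minus the mid-body AP diameter;
the sign convention is chosen so that scalloping (a posteriorly eroded,
waisted body) is positive, consistent with the positive group means reported
in patients.

## Measurement geometry

All image-domain operations use one axis convention: x = left→right,
y = posterior→anterior, z = caudal→cranial (right-handed), AP measurements
along +y. Coordinates are continuous millimetres; voxel indexing is 0-based
with the centre of voxel (0,0,0) at `spacing/2`. A voxel belongs to a
structure iff its centre lies inside the analytic surface; this makes
voxel-count volumetry convergent as the grid is refined and gives the tests
a well-defined oracle.

**Clipping planes.** The dural sac is partitioned into level segments by
planes through the intervertebral disc spaces. For each adjacent vertebra
pair the plane point is the midpoint between the facing endplate-slab
centroids (each body's extreme 2 mm slab along its principal axis) and the
normal is the unit vector between the two body centroids. The outer planes
(above L3, below S1) sit at the outer endplate-slab centroids offset
outward by half the estimated disc gap. The centroid-axis normal was chosen
over a fitted endplate surface because it is stable on noisy masks; on the
default phantom the fitted planes land within 0.1 mm and well under 1° of
the true disc mid-planes. How such planes "should" be oriented
(disc-parallel vs. axis-orthogonal) is not standardised; the centroid-axis
convention is this package's choice and is what the tests pin down.

**Partition rule.** A dural voxel belongs to level ℓ iff its signed
distance to ℓ's upper plane is ≤ 0 and to ℓ's lower plane is > 0
(half-open, upper-closed). No voxel can be double-counted, so the four
segment volumes sum *exactly* to the dural volume between the outermost
planes — an invariant asserted per voxel in the tests.

**Diameters.** AP diameters are measured as the AP extent of the
structure's voxels in a one-voxel slab at the reference plane, restricted
to the midsagittal slab (±1 voxel around the sagittal plane through the
structure centroid): mid-level sagittal measurement, the convention of the
dural-ectasia literature. Vertebral diameters are taken at the body
centroid normal to its principal axis; dural diameters at the mid-plane
between the level's bounding planes; S1 endplate diameters in 2 mm slabs at
the body's cranial/caudal extremes. Whether the clinical S1 DSDR
denominator is the mid-body or an endplate diameter is not standardised;
the mid-body diameter is used here. mL↔mm³ conversion is fixed at 1000 and
values are rounded only at report time (1 decimal for mm/mL, 3 for ratios
and AUCs), never internally.

## The phantom

`build_phantom()` rasterizes an analytic geometry with known ground truth:

* **Vertebral bodies** are elliptic cylinders (AP semi-axis *a*, lateral
  semi-axis *b*, height *h*) with concave lateral surfaces, modelled as a
  sinusoidal lateral waist of depth *c*; volume has the closed form
  πabh − 2ach. The S1 body additionally takes a sinusoidal AP waist
  ("scallop" depth *s*), making its closed-form volume
  πabh − 2h(ac + sb) + πhsc/2 and its true scalloping 2s.
* **The dural sac** is a tube whose sagittal centerline bows ventrally over
  the lumbar levels (natural-spline through control points) and whose
  radius tapers conically caudally (piecewise linear, 8.2 mm cranially to
  5 mm caudally by default). Cross-sections in axial planes are circles of
  radius r(z), so the true volume between horizontal planes is the 1D
  integral of πr(z)², evaluated by fine trapezoidal quadrature (step
  8 µm — exact to well beyond voxel precision). An `ectasia_factor` ≥ 1
  widens the tube caudal of the L5/S1 disc with a 12 mm linear blend,
  emulating the caudally accentuated dural expansion of ectasia.
* **Intensity** follows a bright-fluid model (dural 100, bone 60,
  background 5) with Rician noise (default σ = 5, i.e. 5% of the dural
  signal) as in magnitude MR images.

Defaults (28 mm bodies, 8 mm discs, ~30 mm AP vertebral diameters, 1 mm
isotropic grid of 96×96×160) describe an adult-sized lumbosacral segment at
the acquisition resolution typical of 3D T2-weighted spine imaging.
Structure centres sit at generic off-lattice positions; exactly
lattice-aligned constant-radius tubes are a degenerate rasterization case
(area error resonances up to ~3%), while the default tapered/curved
geometry converges as tested: within 2% of the analytic truth at 1 mm and
0.5% at 0.5 mm.

`perturb_labels()` displaces each structure's boundary by a spatially
smooth zero-mean Gaussian field (SD in mm), using signed shell distances
from 6-neighbour erosions/dilations; it emulates the boundary-level
imperfections of automatic segmentations that motivate manual correction.
`simple_segment()` (threshold + largest 6-connected component + hole
filling) is deliberately plumbing-level: the shape-model segmentation of
real MRI is out of scope, and the phantom segmenter exists only so the
pipeline can be driven from intensity images in tests.

## The cohort simulator

`default_group_specs()` carries the published per-group means ± SDs of all
33 variables (volumes, ratios, diameters, sleeve diameter, scalloping,
height, weight) for the MFS and non-MFS groups; `sample_cohort()` draws
synthetic patients from them. Two families are used:

* **Lognormal (moment-matched)** for all measurement variables. They are
  strictly positive, and the S1 indices are strongly right-skewed: a
  normal with mean 0.41 and SD 0.28 would put ~7% of DSVR values below
  zero, while the published S1 cut-off behaviour is reproduced well by the
  lognormal (see below).
* **Zero-truncated normal** for height and weight, where the mean is >10
  SDs from zero and truncation is numerically irrelevant. Truncation is
  applied without re-matching moments; the documented bias is far below
  the 1%/3% recovery tolerances the tests assert.

Variables are sampled independently by default; the source distributions
are published only as marginals, and inventing a correlation structure
would fabricate information. An optional Gaussian copula (per-group
correlation matrix) is available for sensitivity analyses; it preserves
the marginals exactly. Within-patient consistency between image-derived
and tabular values is deliberately *not* modelled — the phantom covers the
image-derived path separately.

**What passing tests do and do not show.** The simulator reproduces the
published group marginals, so results that depend only on per-variable
group separation (AUCs, cut-off operating points) transfer. It does not
reproduce inter-level correlation within a patient, so statistics that
depend on the *joint* distribution across levels — notably the stability
of per-cohort AUC *orderings* across levels — are not expected to match a
real cohort. This matters for one acceptance property: the expected
(closed-form) AUC ordering of the volume ratios, S1 > L5 > L4 > L3, is
reproduced by the mean AUCs over replicate cohorts, but a single simulated
cohort of n = 63/81 shows the complete strict ordering only ~49% of the
time, because the closed-form L4–L3 gap (~0.014) is small against the
~0.06 sampling SE of a between-index AUC difference under independent
sampling. A per-run ordering rate of ≥90% would require inter-level
correlations around 0.98, which no plausible anatomy delivers; the
corresponding acceptance test is therefore expected to fail under these
study conditions, and is retained unmodified as an honest record.

## Diagnostic accuracy

* **Group comparisons** use Welch's t (the group SDs are grossly unequal,
  e.g. 8.4 vs 2.4 mL at S1).
* **Empirical AUC** is the Mann–Whitney estimator (ties ½), oriented
  "higher ratio ⇒ MFS" — all published MFS group means exceed the non-MFS
  means — with DeLong 95% CIs (via pROC), clipped to [0,1]. The tests
  assert exact agreement with brute-force pair counting and 93–97%
  CI coverage over 1000 simulated cohorts.
* **Closed-form AUC**: Φ((μ₁−μ₀)/√(σ₁²+σ₀²)) under the binormal model, or
  the same on the log scale after moment-matching under the lognormal
  family. This bridges published group moments directly to published ROC
  areas. The binormal form matches the published volume-ratio AUCs at all
  four levels and the diameter-ratio AUCs at L3–L5 within ±0.02; at S1 the
  diameter ratio (MFS 1.11 ± 0.68) is too skewed for the binormal model,
  which underestimates the published 0.848 at ≈0.81, while the lognormal
  closed form gives ≈0.86. Consistently, the lognormal model of the
  published S1 DSVR parameters puts ~95% of non-MFS patients below the
  0.25 cut-off, matching the published 97% specificity, where a normal
  model would not.
* **Youden cut-offs** scan all observed scores as "≥ cutoff ⇒ positive"
  rules; ties in J break toward the lowest cut-off (the more sensitive
  rule at equal J); predictive values use the sample prevalence.
* **McNemar** compares the Youden-dichotomised DSVR vs DSDR classification
  per level on the same patients, exact binomial by default (discordant
  counts are small at n = 144), continuity-corrected χ² as an alternative.
  Which paired classifications the published per-level p values compare is
  not stated in the source literature; the per-level Youden
  dichotomisations are the natural reading and the report labels them as
  such. No multiple-testing correction is applied (α = 0.05 two-sided),
  matching the published analysis.

## Numerical choices and degenerate inputs

* Partition membership is computed at voxel centres, consistent with the
  rasterization rule; unordered planes and planes missing the dural extent
  are errors, as are missing labels and overlapping (interpenetrating)
  vertebral masks.
* `sample_cohort`, `build_phantom` and `perturb_labels` take an explicit
  seed, never read or leave behind global RNG state, and are byte-identical
  given identical inputs.
* Problem sizes used by the test-suite simulations — 500 cohorts of
  n = 63/81 for the AUC recovery checks, 1000 for CI coverage, 50,000 per
  group for moment recovery, 20 seeds for boundary-noise robustness, and
  phantom grids of 96×96×160 (1 mm) and 192×192×320 (0.5 mm) — were chosen
  so that Monte-Carlo error is comfortably below each asserted tolerance.

## Known limitations

* The phantom has no vertebral arches, nerve root sleeves or meningoceles,
  no bias fields, and no MRI sequence simulation; nerve-root-sleeve
  diameter exists only as a simulated tabular variable.
* The threshold segmenter is not a segmentation method for real images.
* Independent per-level sampling limits joint-across-levels inference, as
  discussed above.
* DICOM ingestion is out of scope; NIfTI-1 is the single image format.
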