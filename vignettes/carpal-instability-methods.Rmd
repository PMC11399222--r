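---
title: "Measuring carpal instability from segmented wrist radiographs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring carpal instability: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`carpalign` starts where a segmentation model stops: its input is a set
of per-bone label masks of a wrist radiograph (AP/PA and/or lateral
view) with a sidecar declaring the pixel spacing in mm/px, the view
type, and the patient age. Everything downstream of ingestion is in
millimetres; pixels never leak past the IO layer. The coordinate
convention is the image convention throughout: x rightward, y downward,
origin at the top-left pixel center, so "proximal" is larger y on an
upright frontal view.

Seven bones carry all measurements: scaphoid, lunate, triquetrum,
capitate, hamate, third-metacarpal base and distal radius. Missing
bones are reported, not fatal — each measurement declares which bones
it needs and becomes "unavailable" without them.

# Shape machinery

## Point distribution models

Each bone outline is modelled as a point distribution model (PDM):
training contours are resampled to n = 64 arc-length-uniform landmarks,
aligned by generalized Procrustes analysis (similarity transforms,
consensus mean at unit centroid size), and decomposed by PCA on the
flattened landmark vectors. The model frame is rescaled to the mean
training centroid size so model-frame distances are in mm. The mode
count k is the smallest number of modes reaching the variance target
(default 0.95), capped at min(2n − 4, m − 1) for m training shapes —
the similarity-invariant dimension of 2-D shape space. n = 64 is a free
parameter: it resolves the bone outlines at roughly 1 mm landmark
spacing, comfortably below the 3.0 mm clinical threshold granularity,
while keeping the cyclic correspondence search cheap.

Fitting a model to a new contour alternates two closed-form steps:
similarity pose estimation (complex least squares) and projection of
the pose-normalized observation onto the mode subspace with
coefficients clamped to ±3√λ — the standard PDM plausibility
constraint that keeps every reconstruction a "plausible normal" shape.
Correspondence between the resampled contour and the model landmarks is
found by a cyclic search: all n integer start offsets in both
traversal directions, scored by the similarity-invariant Procrustes
distance to the model mean, followed by a grid-based fractional
refinement (offsets ±0.9 samples in 0.1 steps). Two consequences of
this design are worth knowing:

- Candidates whose implied pose rotation exceeds ±135° are rejected.
  Radiographs arrive upright with a declared view, so a bone cannot be
  upside down; without the constraint, the nearly 180°-symmetric
  proximal-row bones can lock onto a flipped correspondence that swaps
  their radial and ulnar facets.
- The model landmarks are assumed to be approximately arc-length
  uniform along the outline (true for models trained by
  `trainModels()`, which resamples all training contours the same way).

The fitted landmarks returned to the caller are the regularized model
reconstruction mapped into the image frame; named facet index ranges
(articular surface segments such as `scaphoid_lunate` or
`capitate_mc3`) transfer from the model by index.

## Why contour-only models

The package fits shapes to binary segmentations, not to gray-level
radiographs, so no appearance term is needed: a contour-only PDM is the
appearance-free core of an active shape/appearance model and is exactly
identifiable from label masks.

# Measurements

* **SL distance** (AP/PA): Euclidean distance between the arc-length
  midpoints of the facing scaphoid–lunate facets (the
  midpoint-to-midpoint chord, not the facet-normal distance).
* **SL angle** (lateral): angle between the scaphoid long axis and the
  lunate mid-plane axis. The scaphoid axis is the major eigenvector of
  the landmark second-central-moment matrix, oriented toward the distal
  pole; an eigenvalue ratio below 1.05 is flagged as ambiguous. The
  lunate axis joins the midpoints of its radius-facing and
  capitate-facing facets.
* **CL angle** (lateral): angle between the capitate axis (midpoint of
  the capitolunate facet → midpoint of the capitate–metacarpal-III
  facet) and the lunate axis.

Angles are unsigned, in [0, 180), between canonically
distally-oriented directions. Classification uses strict exceedance:
SL distance abnormal iff above 3.0 mm (neutral and clenched-fist
AP/PA) or 3.7 mm (ulnar-deviated); SL angle abnormal iff outside
30–60° with boundaries normal; CL angle abnormal iff above 30°, with
30.0° exactly normal. The clenched-fist fallback to the neutral limit
is an assumption and is echoed in every report. Pediatric SL-distance
limits (ages 6–14) are age-band values the user must supply from the
pediatric reference literature; the shipped table is intentionally
empty and pediatric cases without a covering band are returned
unclassifiable rather than silently misclassified.

# Carpal arc analysis

Gilula's arcs are built from the fitted facet surfaces on the neutral
AP/PA view only: arc I concatenates the proximal articular surfaces of
scaphoid, lunate and triquetrum; arc II their distal surfaces; arc III
the proximal surfaces of capitate and hamate. Each arc is resampled to
100 arc-length-uniform points, radial to ulnar.

Interruption detection compares each observed arc with its PDM
reconstruction as a hypothetical non-interrupted shape: the observed
arc is similarity-aligned to the arc model, projected with ±3√λ
clamping, and mapped back. Per-point z-scores divide the model-frame
residual by a per-landmark residual scale σ_i; the disruption score is
the fraction of all arc points (300 with all three arcs) with z ≥ 2,
and a score at or above 0.11 (11%) is called an interruption. This
score was chosen because it is percentage-valued, localizable (the
exceeding runs become markers), and monotone in every z value. z is
computed in the pose-normalized frame so the score is invariant to
global similarity transforms; the displacement vectors are mapped back
to the image frame for display, where warm colors mark significant
deviations.

Two calibration choices matter:

* **σ_i is the RMS magnitude of the training reconstruction
  residuals** (the SD of the zero-mean residual vector), floored at
  max(0.05 mm, observed). An SD about the mean magnitude would inflate
  z for held-out normals, since residual magnitudes are a folded,
  non-negative quantity.
* **Arc models are trained through the measurement chain itself**
  (mask → contour → bone-PDM fit → arc construction), not on exact
  ground-truth arcs, so σ_i encodes the realistic per-point noise of
  the pipeline and held-out normal arcs score z ≈ 1 when contour noise
  is present. On perfectly clean synthetic data the pipeline noise is
  below the 0.05 mm floor, z is floor-dominated and conservative
  (held-out mean z ≈ 0.1), which only widens the margin between
  normals and interruptions.

The arc training set deliberately includes widened-but-aligned normal
variants, so pure joint-space widening (arcs that only lengthen) stays
inside the mode subspace and scores low — widening without proximal
subluxation is not an interruption.

# The synthetic wrist generator

The generator is the package's substitute for clinical data: it builds
AP/PA and lateral bone contours from hand-designed smooth polygon
templates (60–76 vertices per bone, shipped as a JSON fixture so facet
index ranges are stable) and rasterizes them into label masks with a
pixel-center-inside fill.

Constructions guarantee exact ground truth at zero noise:

* the proximal surfaces of the proximal row lie on one circle (radius
  60 mm at unit scale), their distal surfaces on a second, and the
  distal-row proximal surfaces on a third, so the three arcs are
  smooth across bones with known curvature;
* the SL-facing walls of scaphoid and lunate are parallel vertical
  segments sharing one y-range, so their facet midpoints face each
  other exactly and the SL distance equals the applied gap;
* the lateral scaphoid is a mirror-symmetric egg whose principal axis
  is its long axis (the asymmetric pole pins the correspondence), and
  the lateral lunate/capitate carry facets whose midpoints are
  vertically aligned, so rotating the scaphoid about its centroid and
  the capitate about its capitolunate facet midpoint realizes exact SL
  and CL angles.

An interruption is modelled as a proximal translation of the capitate
(optionally the lunate) by `subluxationMm`, the mechanism of a capitate
subluxating into a widened SL space; translations above the declared
1 mm step threshold are labelled interrupted. Infeasible parameter
combinations (overlapping bones) raise an error. Smooth per-vertex
jitter (Gaussian, circularly smoothed over 7 vertices, rescaled to the
requested marginal SD) emulates segmentation noise.

Default cohort conditions (chosen once as a realistic case mix): global
scale U(0.9, 1.1), rotation U(−10, 10)°, SL angle U(35, 55)°, CL angle
U(0, 25)°, normal gaps U(1.5, 2.5) mm with a widened subset at
U(3.5, 4.5) mm, interrupted cases at 3 mm subluxation over gaps
U(3, 5) mm.

What the generator does **not** emulate: anatomical shape variation
between patients (each bone is one template up to similarity), X-ray
projection physics, overlapping bone shadows, or segmentation failure
modes beyond contour jitter. Passing the package's recovery tests
therefore demonstrates the correctness of the measurement chain, not
clinical accuracy: synthetic in-model errors (MAE ≈ 0.14 mm / ≤ 1°)
are far below errors achievable on real radiographs, where anatomy is
out-of-model. The CL angle is recorded unsigned in the ground truth
(the measurement convention cannot distinguish a −20° from a +20°
tilt).

# Evaluation statistics

Differences are prediction minus truth. Limits of agreement are
bias ± 1.96·SD (sample SD); bias and LoA confidence intervals use the
Bland–Altman normal approximations, everything else uses stratified
bootstrap percentiles (1000 iterations by default; strata of 1 mm for
distances, 10° for angles, class labels for detections). Arc accuracy
uses the discrete Fréchet distance (dynamic programming over monotone
couplings) — the arcs are fixed-size point sequences, so the discrete
variant is the natural one. AUC is the pairwise-ordering probability
with half credit for ties; the operating threshold maximizes Youden's
J over the observed score values with ties resolved to the lowest
threshold. Paired permutation tests flip signs of paired differences
with a +1/(iters+1) smoothing so p is never exactly zero; the DeLong
test uses placement-value covariances with a two-sided normal p-value.
The bootstrap CI is the plain percentile interval (not BCa), matching
the 2.5/97.5 percentile convention of the rest of the stack.

# Numerical choices and degenerate inputs

* Sub-pixel contours are the 0.5 iso-level of the binary mask
  (marching-squares style); the boundary sits within half a pixel of
  the true polygon edge and biases outlines slightly outward, which is
  why the SL distance carries a small negative bias (~0.14 mm at
  0.1 mm/px).
* Masks must contain one substantial connected component; specks up to
  max(9 px, 0.5% of the foreground) are discarded as rasterization or
  segmentation debris, anything larger raises a failed-segmentation
  error.
* A 1-pixel mask, an empty mask, a zero-length polyline, coincident
  facet midpoints, a near-isotropic bone (principal-axis eigenvalue
  ratio < 1.05) and exactly opposed axis orientations are all explicit
  errors or warnings, not silent results.
* All randomness (cohorts, jitter, bootstrap, permutation) is behind
  explicit integer seeds; reports are written at fixed precision, so
  identical inputs and seeds give byte-identical report files.

# Problem sizes

The shipped tests and the acceptance script use cohorts sized for a
single CPU: 20 training normals, a 50-case recovery cohort at
0.1 mm/px, and a 100-case detection cohort at 0.2 mm/px. These sizes
put Monte-Carlo error well below the tested tolerances (e.g. MAE
thresholds of 0.2 mm and 2°) while a full run stays around a minute.

# Known limitations

* One template per bone: the PDMs learn pose, scale and the generator's
  parameter family, not population shape variation. On real data the
  models must be retrained on annotated contours.
* The residual floor (0.05 mm) dominates z-scores on noise-free data;
  detection margins are then conservative rather than calibrated.
* A constant ≈1° systematic tilt of the measured SL angle remains,
  inherited from the discretization of the model mean at the training
  resolution; it is well inside the 2° recovery budget but would need
  finer training rasterization to remove.
* The pediatric threshold table ships empty by design.
* Lateral-view arcs, radiolunate angle, ulnar variance and carpal
  height ratio are out of scope (extension points only).
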