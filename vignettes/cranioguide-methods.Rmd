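---
title: "Methods: facial-landmark-guided 10-20 head landmark construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial-landmark-guided 10-20 head landmark construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Consistent placement of fNIRS optodes and EEG electrodes depends on
locating the 10-20/10-10/10-5 scalp coordinate system on each subject's
head, which in turn depends on five cranial fiducials: nasion (Nz), inion
(Iz), the left and right preauricular points (LPA/RPA) and the vertex
(Cz).  Measuring these with a tape is slow and operator-dependent.
`cranioguide` implements the computational core of a camera-guided
alternative: a facial-landmark detector supplies 3D facial points in a
normalized camera frame; a precomputed linear mapping turns them into
subject cranial fiducials; a precomputed atlas 10-20 layout is registered
onto those fiducials by an affine fit; and the result is projected as an
image overlay, frame by frame.  Every stage is a plain R function, and a
synthetic head-population generator replaces the proprietary head-scan
libraries such workflows are normally trained on, so the whole pipeline is
testable from code alone.

## Geometric fiducial construction

Given Nz, LPA and RPA on a head surface mesh, the remaining two fiducials
are constructed under the assumption that Nz, Iz, LPA and RPA share a
plane:

* **Iz** is the far intersection of the mesh with the ray from Nz through
  the midpoint of LPA and RPA.  The *far* hit matters: the near hit is the
  surface adjacent to Nz itself.  The result is coplanar with the three
  inputs by construction (`cranial_coplanarity_residual()` is at
  floating-point level).
* **Cz** is the far intersection of a ray cast from the LPA/RPA midpoint
  along the normal of the fiducial plane, oriented toward the top of the
  head.  The orientation is the cross product of (Iz − Nz) and
  (RPA − LPA).  Descriptions of this construction sometimes speak of an
  "inner product" of the two vectors, but a scalar cannot orient a ray;
  the cross product is the only product of those two vectors that produces
  the superior axis, and that is what `estimate_cz()` computes
  (documented prominently on its help page).  Whether the ray should
  originate at the LPA/RPA midpoint or the Nz/Iz midpoint is not fixed by
  the construction; both lie in the fiducial plane, the difference is
  absorbed by the plane normal, and the choice is exposed as the `origin`
  argument rather than asserted.

In `"five-point"` mode all five fiducials may instead be supplied
independently (e.g. from an atlas); overrides are used verbatim after an
on-surface check (1 mm default tolerance, configurable).

## Mesh geometry primitives

All constructions run on triangular meshes in millimeters
(`tri_mesh()`), which need not be watertight.  Three primitives carry the
whole module:

* `ray_mesh_intersect()` — a vectorized Möller–Trumbore test over all
  faces; hits with ray parameter below `1e-9` mm are rejected so rays
  starting on the surface (as fiducial rays do) never return their own
  origin.
* `plane_mesh_contour()` — plane-triangle section extraction.  Crossings
  are computed once per mesh *edge* and on-plane vertices are kept as
  exact nodes, so segments from adjacent triangles stitch without
  floating-point matching heuristics; this also makes cuts that pass
  exactly through vertices (routine on the symmetric synthetic meshes)
  well-defined.  When the section has several components, the one nearest
  the anchor point wins, ties broken by length; an anchor farther than a
  tolerance (default one quarter of the bounding-box diagonal) from every
  component is an error.
* `arc_between()` / `subdivide_arc()` — sub-arc extraction between
  projected endpoints, traversed in the direction passing nearest a *via*
  point, and linear-in-arc-length interpolation at given cumulative
  fractions, with fractions 0 and 1 mapping to the endpoints exactly.

## 10-20 / 10-10 / 10-5 layout construction

The layout step is implemented as the standard arc-fraction construction
(workflows in this space often delegate it to an external toolbox; here it
is normative and testable):

1. **Sagittal arc**: cut by the plane through Nz, Cz and Iz; the upper arc
   Nz→Cz→Iz is subdivided at 10/30/50/70/90 % (10-20), every 10 %
   (10-10), every 5 % (10-5).  The 50 % point *redefines* Cz — the
   incoming Cz only seeds the cutting plane, because the 10-20 convention
   defines Cz by arc fractions.  The discrepancy between the two
   definitions is reported as an attribute.
2. **Coronal arc**: plane through LPA, the redefined Cz, and RPA;
   fractions measured from LPA (T7 at 10 %).
3. **Circumferential ring**: the least-squares plane through the four
   10 %-level anchors (Fpz, T7, Oz, T8) — on real heads those four are
   generally not exactly coplanar — cut and parameterized from Fpz toward
   T7; ring labels sit at fractions of the total ring length (Fp1 at 5 %,
   F7 at 15 %, …).
4. **Transverse rows** (F7–Fz–F8, P7–Pz–P8, and at higher densities the
   FT/TP/AF/PO rows): plane through the three placed anchors, subdivided
   at quarter steps (10-20) or eighth steps (10-10).

The label/fraction/region catalogue is a generated data table
(`tentwenty_catalogue()`), and densities nest exactly: shared labels have
identical generating arcs and fractions, which the tests verify to 1e-9
on a common mesh.  The shipped 10-5 table is a documented *partial*
superset — full 5 % resolution on the sagittal and coronal arcs plus
nine-point AF/PO rows, without ring interleaves or the extra transverse
rows of the complete extended nomenclature, and without below-ring rows
(T9, FT9, …) at any density, since the constructed ring is the lowest
curve.  All consumers tolerate layouts with missing labels.

Anterior/posterior region tags follow the coronal-medial-line convention:
labels on the T7–C3–Cz–C4–T8 line count in **both** regions; everything
between that line and Nz is anterior, everything toward Iz posterior.

On a sphere with canonical fiducials every sagittal, coronal and ring
label has a closed-form great-circle position; the test suite checks the
constructed layout against those closed forms at several mesh refinements
and requires the deviation to shrink monotonically with refinement.

## The face-to-head linear map

Per camera view, the conversion between head-model millimeter coordinates
and the detector's normalized frame is modeled as an affine transform
fitted by least squares over ten designated correspondence landmarks
(nasion, eye corners, nose tip and sides, mouth corners;
`view_correspondence_indices()` is an editable table).  Least squares is
used without outlier handling; the fit is exact whenever an exact affine
relation holds.

The regression itself maps a flattened vector of `Nf = 20` selected
facial points (x, y, z triplets in subset order) to each cranial target
c ∈ {Iz, LPA, RPA, Cz}:

$$ P_c = F A_c + \mathbf{1}\, b_c, \qquad A_c \in \mathbb{R}^{3N_f \times 3} $$

stacked over all subjects and views under the rigid-body assumption that
one map serves every view.  The normal-equations/pseudo-inverse solution
is the reference *semantics*; the implementation solves the equivalent
three independent per-coordinate least-squares problems by QR, and the
test suite pins the two against each other on random instances.  Nz is
never regressed: the camera convention's point #168 (0-based; row 169 in
this package's 1-based indexing — every fitted map and JSON file records
its index base explicitly) coincides with the nasion and is copied
verbatim at prediction time.

An optional ridge penalty (on `A_c` only, never on `b_c`; default 0)
exists because low-dimensional synthetic populations can produce
rank-deficient designs: an ellipsoid family has three shape degrees of
freedom, so small populations span the 61-column design only through
second-order shape effects.  With `ridge = 0` such designs fail loudly
rather than silently pseudo-inverting.  The default 20-point subset spec
is an editable table naming the facial feature groups it spans; the spec
is stored inside every fitted map for reproducibility.

Facial depth (z) is used as the detector provides it, without rescaling.
Note that the model is affine in landmark *coordinates*, not a
rigid-motion model: translating all facial inputs translates predictions
by `A_c`-dependent amounts, not by the same offset (a property the tests
assert rather than hide).

## Atlas registration

Predicted cranial fiducials and atlas fiducials are matched by a
least-squares affine (`fit_registration()`), which then carries the
atlas's precomputed layout onto the subject.  Two details:

* In three-point mode Nz/Iz/LPA/RPA are coplanar by construction, and
  four coplanar points cannot determine a 3D affine, so **Cz is always in
  the correspondence set**; the mode records how Iz was derived, nothing
  more.  Coplanar-only input raises an explicit degeneracy error.
* The fit runs directly across frames (atlas millimeters to subject
  normalized coordinates): the affine absorbs the scale, so no separate
  unit conversion step exists to get out of sync.

A structural caveat verified by the tests: the arc-fraction layout
construction commutes with *similarity* transforms (rotation, uniform
scale, translation) but not with general anisotropic affines, which
change arc-length fractions.  The registration self-consistency check
therefore uses a similarity-transformed subject; for real heads the
residual between "register the atlas layout" and "recompute on the
subject mesh" is part of the method's error budget, exactly as in the
workflow this package models.

## Frame stream stabilization

Detector jitter is mitigated by a moving average over the last `w` frames
(`stabilizer()`; `w ∈ {3, 5, 8, 10}` are the typical settings, any
positive integer works).  Averaging is applied to the *facial* landmarks
before prediction — whether to average inputs or outputs is genuinely
ambiguous in such pipelines; input-space averaging was chosen because
every downstream stage then benefits, and `process_stream()` exposes the
stages so output-space averaging can be composed by hand if wanted.  For
i.i.d. jitter of sd σ the steady-state output sd is σ/√w (the tests
check this within 10 % at 10,000 frames), the reduction is monotone in
`w`, and a step change in the input reaches the new steady state after
exactly `w` frames — the lag users trade against stability.  Frames with
no detected face are skipped without touching the buffer.  Registration
is refit every frame by default (`refit_interval` trades accuracy for
speed).

## The synthetic head population

The generator replaces a licensed library of real head scans; all its
outputs are pure functions of (parameters, seed).

* **Meshes** are geodesic spheres built by subdividing a regular
  octahedron, scaled anisotropically into ellipsoids.  The octahedral
  base is deliberate: the six axis points are exact mesh vertices at
  every refinement, so the canonical cranial truth (Nz = (a,0,0),
  Iz = (−a,0,0), LPA/RPA = (0,±b,0), Cz = (0,0,c)) lies exactly on the
  surface, and closed-form sphere oracles are meaningful to sub-edge
  tolerances.
* **Facial truth** is 24 points at fixed angular positions on the
  anterior surface (nasion, eye corners, brows, nose, mouth, chin, jaw,
  cheeks, temples), snapped onto the mesh by center-ray casting; point 1
  is the nasion, mirroring the detector convention's Nz-coincident point.
  The 24-point convention is a superset of the default 20-point
  regression subset, so subset selection is genuinely exercised.
* **Population priors**: semi-axes are drawn from independent Gaussians
  with mean (95, 75, 88) mm and sd (6, 5, 5) mm (truncated at ±4 sd) —
  adult head half-length/half-width/half-height with moderate
  inter-subject variation, chosen once so that facial-to-cranial geometry
  stays in the near-linear regime the linear map assumes.
* **Views**: a nine-view grid, three vertical positions (pitch
  +20/0/−20°) × three horizontal (yaw −30/0/+30°).  Each view applies
  the rigid rotation and then an orthographic normalization into [0, 1]
  by the rotated bounding box with a 10 % margin.  A real detector's
  normalization is defined by its network and is not recoverable; this
  documented stand-in preserves the property that matters — an exact
  per-view affine between head and camera frames — which is what the
  frame-conversion fit must recover.
* **Jitter** is added to facial landmarks only; cranial truth stays
  exact, mirroring pipelines where reference fiducials are curated while
  facial points are detector output.

What the generator does **not** emulate: hair and headwear occlusion,
perspective distortion, detector bias fields, asymmetric anatomy, and
real shape variability beyond three ellipsoid axes.  Passing tests
therefore demonstrate the *algorithms* are correct and well-conditioned,
not that real-world errors will be small; population error magnitudes on
these synthetic heads are much smaller than on real heads.  One visible
symmetry artifact is worth knowing about: ellipsoid meshes are
antipodally symmetric, so LPA + RPA maps to a constant in every
normalized view and the two regressions share residuals row for row —
LPA and RPA error distributions are consequently identical rather than
merely similar.

## Validation harness

`kfold_split()` always splits by subject, never by view, so a subject's
views are never divided between train and test.  `evaluate_cranial()`
pools per-landmark Euclidean errors over folds (exactly one prediction
per subject–view–landmark) and summarizes by median and interquartile
range — the robust summaries appropriate for these skewed error
distributions — grouped by landmark, view, subject and fold; raw errors
are always stored so summaries are recomputable.  `evaluate_layout()`
scores label intersections and applies the both-regions convention for
medial-line labels.  `noise_uncertainty_experiment()` reruns the whole
per-frame pipeline over jittered renders per window length and reports
per-label positional standard deviations.  Grouping is by arbitrary keys;
the package ships no demographic claims, and statistical tests on group
differences are left to the standard R functions users already have.

## Numerical choices

* Tolerances are relative to the geometry: contour node classification at
  `1e-9` of the bounding-box diagonal, duplicate-point merging at `1e-9`
  of the polyline extent, ray self-hit rejection at `1e-9` mm.
* Contour component selection: nearest to anchor, ties to the longer
  component; branching (non-manifold) sections are an error, not a guess.
* Least squares everywhere is QR-based; rank deficiency is an error
  unless ridge is requested.  Affine fits require four non-coplanar
  correspondences.
* JSON writers emit 17 significant digits, so coefficient round-trips are
  bit-exact.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at desk scale, sizes chosen as the package's own study conditions: 100
ellipsoid subjects × 9 views (geometry-mode study, 5-fold CV), 50
subjects × 9 views (identifiability), 100 random instances (solver
oracle), sphere refinements 3–5 (layout closed forms), 10,000 frames
(stabilizer statistics).  `scripts/acceptance.R --seed <s> --out <json>`
recomputes all headline quantities from scratch at those sizes.

## Known limitations

* The 10-5 catalogue is a partial superset (see above).
* Layout registration is exactly self-consistent only under similarity
  transforms; anisotropic subjects incur a method-intrinsic residual.
* The live-detector adapter is out of scope: streams enter as JSON-lines
  recordings, and nothing in the test surface touches a camera.
* Random-forest / neural-network predictors are deliberately absent; the
  linear map is the implemented and validated predictor, and
  `fit_linear_headmap()`'s contract (a `linear_headmap` with per-target
  coefficients) is the extension point a different predictor would
  implement.
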