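---
title: "Measuring implant migration with rsakit: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implant migration with rsakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsakit)
```

## The measurement problem

Radiostereometric analysis (RSA) measures the migration of a joint
replacement relative to its host bone with sub-millimeter, sub-degree
accuracy. Small tantalum markers (0.5--1 mm) implanted in the bone and
attached to (or substituted by fictive points on) the prosthesis serve as
reference points. Two simultaneous roentgen projections, calibrated
against a cage with markers at known positions, let each marker be
triangulated in 3D. Migration of a prosthesis over time is an early
surrogate for aseptic loosening, so these measurements support implant
safety studies, screening, and diagnostics with comparatively small
patient groups.

`rsakit` implements the full computational chain downstream of marker
detection: stereo calibration and triangulation, rigid-body registration
with its quality metrics, the standardized migration decomposition,
double-examination precision statistics, phantom accuracy experiments,
and guideline-style reporting. Marker *detection* in pixel data, CT image
registration, and model-based pose estimation from silhouettes are out of
scope: inputs are labeled 2D detector coordinates or labeled 3D points.

## Stereo geometry and calibration

The calibration cage defines the global coordinate system. Fiducial
markers lie in the detector plane layer(s); control markers occupy an
intermediate layer. `calibrate_image()` proceeds in two stages:

1. The image plane is the plane of the known fiducial layer. A projective
   2D mapping (homography, estimated by a normalized direct linear
   transform from at least 4 fiducial detections) takes detector
   coordinates to in-plane cage coordinates. A projective rather than
   affine model absorbs detector scale, offset, rotation, and mild
   perspective effects; no lens/film distortion model is fitted (a
   deliberate simplification -- scanned-film distortion correction is not
   modeled).
2. Each control marker, whose 3D position is known, defines a ray through
   its mapped image point; the roentgen focus is the least-squares point
   closest to all such rays (at least 2 controls; the normal equations
   are 3x3). The control *reprojection* residual -- focus-to-control ray
   intersected with the plane, compared against the mapped detection --
   is reported in detector-plane millimeters, and a mean above 0.5 mm
   raises a warning without failing. The plane-scale residual is the
   comparable quantity; the focus-to-ray distance is amplified by the
   plane-to-focus lever arm (roughly 7--8x in the default geometry) and
   is reported separately.

`reconstruct_point()` back-projects a detection in each image into a
focus ray and returns the midpoint of the common perpendicular; the
length of that perpendicular (the crossing-line distance) is a per-point
quality measure, zero exactly when the rays intersect. Rays within 1
degree of parallel are rejected as ill-conditioned. In the noiseless
synthetic geometry the calibrate--triangulate chain inverts the
projection operator to machine precision, which the test suite asserts.

Uniplanar (side-by-side detectors, ~40 degrees between beams; hips,
shoulders) and biplanar (~90 degrees; knees) setups share one code path
and differ only in cage layout. The guideline's published geometry does
not include numeric cage dimensions, so `make_synthetic_cage()` uses a
plausible two-layer layout: a 500 x 300 mm fiducial grid in the base
plane, six control markers 120 mm above it, foci ~1 m from the plane.
Each synthetic detector is related to the cage plane by a deliberately
non-trivial near-similarity homography so that calibration must actually
estimate the mapping.

## Rigid-body registration and its quality metrics

`fit_rigid()` solves least-squares superposition by SVD of the centered
cross-covariance (the Kabsch/Soederkvist--Wedin solution), with the
smallest singular value sign-corrected so reflections are never
returned -- physical marker sets cannot mirror. Weights are accepted but
default to uniform; the guideline is silent on weighting.

Two quality metrics accompany every fit:

* **ME (mean error of rigid-body fitting)** -- the RMS residual distance
  after optimal superposition; it gauges marker stability between
  examinations. The operative upper limit is 0.35 mm.
* **CN (condition number)** -- a collinearity gauge from the singular
  values $s_1 \ge s_2 \ge s_3$ of the centered configuration.
  `rsakit` uses $s_1/s_2$: collinearity ($s_2 = 0$), not planarity, is
  what makes rigid-motion determination singular, and every 3-marker
  body -- explicitly valid per the minimum-marker rule -- is exactly
  planar ($s_3 = 0$), so a ratio against $s_3$ would be infinite for all
  of them. $s_1/s_2$ is 1 for an isotropic cloud, large for
  pearl-string-like configurations, infinite only for collinear ones.
  The operative upper limit is 120. Because published cut-offs sometimes
  carry the unit 1/mm, whose provenance is not reconstructible from any
  printed formula, a `per_mm` scaling (divide by the configuration
  half-extent) can be selected in the configuration and the limit is
  applied on whichever scaling is chosen; the default is dimensionless.

Degeneracy is declared when $s_2/s_1 < 10^{-9}$ (exactly collinear);
orthonormality of rotations is enforced to $10^{-9}$. At gimbal lock
($r_y = \pm 90^\circ$ within $10^{-6}$ degrees) the X/Z rotations are not
separable; the deterministic convention $r_z = 0$ is returned with a
flag.

## The migration computation

Migration is computed in two steps between a postoperative baseline and a
follow-up: first the reference body (bone) of the follow-up is aligned
onto the baseline bone, removing the difference in patient positioning;
the same transform is applied to the follow-up prosthesis; then the
residual transform from the baseline prosthesis to the aligned follow-up
prosthesis is the migration. The construction makes the result exactly
invariant to any rigid repositioning of the patient between examinations,
which the suite asserts to $10^{-9}$ in the noiseless case.

Results are expressed in an anatomic migration frame: by default the
axes coincide with the global frame (X medial, Y superior, Z anterior for
a right-sided measurement, assuming the patient is aligned with the
cage), and the origin sits at the geometric center (marker centroid) of
the migrating body in the baseline examination. The same frame must be
reused for all follow-ups of a patient. Reported quantities:

* signed translations of the origin along the migration axes (mm), and
  Euler rotations about them in the body-fixed XYZ sequence (degrees);
  signs are right-handed, counterclockwise positive looking down each
  axis toward the origin;
* **TT** and **TR**, the Euclidean norms of the translation/rotation
  triples; TR is flagged once any component or the norm exceeds 5
  degrees, beyond which the Pythagorean summary of rotations loses
  validity;
* per-point motions and **MTPM**, the displacement norm of the evaluated
  point that moved most. The evaluated set is the migrating body's
  markers plus any fictive points (e.g. stem tip, baseplate corners)
  registered on the body; ties break lexicographically by point id. MTPM
  is independent of the migration-frame orientation but is an unsigned,
  upward-biased summary: its mean grows with measurement noise and with
  implant size, both of which the phantom experiment demonstrates.

Interval migration (say, from 12 to 24 months) is the component-wise
difference of the two follow-up results -- the guideline's rule -- with
TT/TR/MTPM recomputed from the differenced components and point motions.
Subtraction is exact for translations but approximate for rotations; the
result carries a flag whenever either input has TR > 5 degrees rather
than silently composing transforms.

Left-sided results are converted to the right-side convention before any
aggregation by negating the X translation and the Y and Z rotations (a
mirror through the sagittal plane); norms are unchanged and the
conversion is an involution. RSA (X left, Y superior, Z anterior) and
DICOM LPS (X left, Y posterior, Z superior) frames interconvert by a
fixed proper axis permutation.

## Quality gating, precision, and accuracy

`qc_thresholds()` carries the operative defaults: ME <= 0.35 mm,
CN <= 120, >= 3 markers, TR small-angle limit 5 degrees, >= 25% of
patients with double examinations, >= 150 DPI and >= 8-bit detectors,
CT slice < 1.0 mm and pixel < 0.5 mm, scheduling windows of +/-14 days
before 12 months and +/-10% from 12 months on. All comparisons are
inclusive -- a value exactly at a limit passes -- because the limits are
stated as bounds.

`qc_gate()` produces the *concise* dataset (rows meeting ME/CN/marker
criteria on both bodies) and the *complete* dataset (everything); both
should be analyzed and differences discussed. Optionally a result whose
CN exceeds the limit but that retains at least 4 stable markers (ME
within limit) is kept with a flag. Every exclusion carries a
machine-readable reason that feeds the flow report, whose conservation
invariant (expected = analyzed + missing, reasons summing to missing)
holds on every run.

Double examinations -- two same-day acquisitions with repositioning --
have zero true motion, so the measured migration between them estimates
the measurement error. `double_exam_stats()` reports, per group and
outcome, the number of pairs, mean (bias) and sample SD (precision,
n - 1 denominator). Phantom accuracy against exact gold-standard poses is
summarized by `accuracy_vs_gold()` as the mean (trueness) and SD
(precision) of signed differences for the six components and of the
differences of the unsigned summaries (MTPM/TT/TR). Bland--Altman limits
of agreement (bias +/- 1.96 SD of paired differences) serve method
comparison when no gold standard exists.

`sample_size()` uses the two-sample normal-approximation formula
$n = 2 (z_{1-\alpha/2} + z_{1-\beta})^2 \sigma^2 / \delta^2$ per group,
rounded up and then inflated by $1/(1 - \text{dropout})$; the detailed
worked appendix it paraphrases is not reproduced here, so the standard
formula was chosen and documented. `posterior_revision_risk()` is the
odds-form Bayes update through the likelihood ratio of a
continuous-migration classification; `classify_migration()` itself takes
a *study-chosen* threshold deliberately -- no default is supplied because
none is prescribed.

## What the synthetic generator emulates -- and what it does not

`gen_study()` produces full longitudinal studies: per patient a bone
cloud (6 markers, 45 mm spread) and prosthesis cloud (4 markers, 25 mm
spread, plus two fictive points), baseline within 2 weeks of surgery,
follow-ups at 6 weeks and 3/6/12/24 months with scheduling jitter inside
the protocol windows, same-day doubles for a configured fraction of
patients, alternating sides, per-coordinate Gaussian marker noise,
Bernoulli occlusion, a Gaussian random-walk instability drift of bone
markers (which drives ME growth and exercises the quality gate), and
exponential dropout. True trajectories follow either a plateau model,
$m(t) = M (1 - e^{-t/\tau})$ per component (default $\tau$ = 120 days),
or a continuous model, rate x t/365 -- quantitative forms of the two
qualitative screening categories. All randomness flows from a single
seed; identical seeds give identical studies.

Two generator assumptions deserve emphasis. First, baseline positioning
varies by table offset only (no rotation): the anatomic migration frame
is tied to the cage frame through patient alignment at baseline, and a
rotated baseline would rotate the migration axes themselves, making
per-component ground truth ill-defined. Follow-up repositioning includes
small rotations, which the bone alignment removes exactly. Second,
`gen_study()` works directly with 3D coordinates; the projection and
triangulation stage is exercised end-to-end by
`run_phantom_experiment()` instead, which projects both bodies through
the synthetic stereo geometry with detector noise, calibrates every
exposure from its own cage detections, triangulates, and compares the
computed migration against the exact applied poses.

Passing tests on these simulations therefore show that the computational
chain is correct and well-calibrated under idealized noise; they do not
show robustness to what the generator does not model: marker detection
errors correlated across markers, film/detector distortion, CT metal
artifacts, systematic marker migration within bone (as opposed to random
drift), or missed/false detections.

## Numerical choices and problem sizes

Tolerances: orthonormality and Euler round-trip $10^{-9}$; degeneracy
$s_2/s_1 < 10^{-9}$; near-parallel-ray rejection at 1 degree; homography
estimation uses Hartley normalization. The default test suite runs the
phantom experiment at 7 poses x 1--20 replicates and the acceptance
checks at 100 replicates (700 full stereo migrations, ~30 s), 200
random rigid-fit instances against a Levenberg--Marquardt oracle, and
100 simulated double-examination pairs -- sizes chosen so the whole
suite completes in a few minutes on one core while keeping Monte-Carlo
bands tight enough to be meaningful. The precision-recovery check pools
the SD over the six signed components (594 degrees of freedom) before
comparing against the 95% chi-square band: per-component 95% bands would
flag one component in vain in roughly a quarter of correct runs.

## Known limitations

* The CN unit ambiguity is resolved by configuration, not by fiat; users
  comparing against historical cut-offs must know which convention their
  software used.
* Interval migration by subtraction is the reporting convention, not a
  transform composition; for large rotations both are provided
  conceptually but only subtraction is computed, with a flag.
* The checklist report computes what is derivable from data
  (timing statistics, quality summaries, flow counts) and flags the rest
  as missing; it does not parse manuscripts.
* CT-RSA support covers coordinates in the LPS frame and acquisition
  metadata validation; image registration quality measures for CT-RSA
  are an open research question and are not modeled.
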