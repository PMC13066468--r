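---
title: "Methods: three-view 3D posture tracking and gaze analysis for zebrafish dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-view 3D posture tracking and gaze analysis for zebrafish dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fintrack3d implements the post-detection half of a 3D tracking rig for pairs
of adult zebrafish filmed by three orthogonal, synchronized cameras: a top
camera (view `XY`) and two side cameras (`YZ`, `XZ`) observing a 25 cm cage at
140 Hz. Upstream detectors are assumed to provide, per frame, up to two
three-point 2D skeletons per view (head tip, pectoral-fin center, tail base —
as a multi-animal pose estimator such as SLEAP would) and a whole-video
top-view centroid-plus-identity table (as an identity tracker such as
idtracker.ai would). The package turns those into identity-consistent 3D
skeleton tracks and dyadic gaze statistics. Because the camera stack itself is
out of scope, a first-class synthetic-data generator reproduces every input
with known ground truth.

```{r setup}
library(fintrack3d)
```

## Polynomial calibration

The mapping between pixel and world coordinates is modeled by five polynomial
regressions fitted to bead-board correspondences (a 7 × 7 board of 49 beads,
photographed in several orientations and pooled into one fit):

* `to_world`: all six image coordinates (three views × `(u, v)`) to world
  `(x, y, z)`, degree 2;
* `to_views`: world `(x, y, z)` to the six image coordinates, degree 2;
* three view maps: the four coordinates of two views to the two coordinates
  of the remaining view, degree 3.

Each output is an unregularized least-squares fit over the *full* monomial
basis of the given total degree, including all cross terms — cross terms are
what absorb the perspective and refraction coupling that a product of
single-axis models could not. Pixel-domain inputs are affinely standardized
inside the map (stored, re-applied at prediction time) and the design matrix
is column-equilibrated before solving, purely for numerical conditioning.

Two numerical choices deserve emphasis:

* **Minimum-norm solutions.** Consistent multi-view image triplets lie on a
  3-dimensional variety inside R^4 or R^6, so the monomial design matrices of
  the image-domain maps are *structurally* rank-deficient (exactly so for
  ideal orthographic cameras). The fits therefore use the SVD pseudoinverse;
  predictions on consistent inputs are unaffected, but individual
  coefficients of the image-domain maps are not identifiable and should not
  be interpreted. Coefficients of `to_views` (world-domain input, full-rank
  design) are identifiable and are what the parameter-recovery tests check.
* **Error policy.** Too few beads for the requested degree raises an
  underdetermined-fit error naming the deficient map; a bead cloud that is
  coplanar in world space, or collinear in a view, raises a
  degenerate-geometry error. Rank deficiency *caused by the view geometry
  itself* is, by the argument above, normal and silent.

Missing coordinates never raise errors in the mapping functions: any missing
input coordinate yields a missing output (the propagation rule the rest of
the pipeline relies on).

Conventions: world origin at the tank floor center, right-handed axes, cm;
pixel origin top-left, px. View `XY` images world `(x, y)`, `YZ` images
`(y, z)`, `XZ` images `(x, z)`.

## Cross-camera identity registration

Per frame, each view reports up to two skeletons in arbitrary order; the
assignment of detections to fish must be made consistent across views. The
package enumerates candidate pairings by fixing the detection order of the
top view and permuting the two side views independently — 2 × 2 = 4
candidates for a full two-fish frame, fewer when detections are missing — and
scores each candidate with a reprojection cost: project both skeletons from
two source views into the third through the view maps, project back to each
source, and average the pixel distance from the reprojected body points to
the originals over present points, the two fish, and the two source cameras.

One design choice was genuinely open: which two views act as sources. Any
single fixed choice leaves one view's observed coordinates out of the cost
entirely, which makes the pairing to that view unscorable — the 4-candidate
search would be blind to it. The cost is therefore averaged over the three
source-pair configurations (each view takes the target role once). Within
each configuration the formula is exactly the two-source round-trip average
described above; the outer average makes every pairing decision observable.

The lowest-cost candidate wins; ties (which occur only in degenerate
geometry) prefer the previous frame's accepted assignment, then the first
candidate in enumeration order. Frames whose best cost exceeds
`reg_cost_max_px` (default 10 px) are discarded and flagged `REG_COST`.

## Fusion and 3D reconstruction

Registered skeletons carry no persistent identity; the top-view centroid
table does. Each skeleton's top-view pec point is matched to the nearest
centroid, greedily by ascending distance, one skeleton per centroid; matches
farther than `fuse_cost_max_px` (default 15 px) are rejected and the frame is
flagged `FUSE_COST` for the unmatched identity. Greedy matching on a 2 × 2
problem is tested against the brute-force matching it implements.

A body point is reconstructed to 3D through `to_world` only when it is
present in all three views. The view maps make it possible to impute a point
missing in exactly one view; because it is not clear that production use
should ever silently manufacture data, that mode exists
(`impute_missing_view = TRUE`) but is off by default.

## Quality control

The QC stage operates on 3D track tables in a fixed order — anatomy filter,
jump detection, gap closing, smoothing — enforced by `run_qc()`. Jump
detection must see raw displacements, and interpolation must precede
smoothing; permuting the stages changes the result and is not offered.

**Anatomy filter.** Skeletons whose head–pec distance exceeds 1.4 cm or whose
pec–tail distance exceeds 2.5 cm are treated as erroneous detections. The
distal point of the offending segment (head, respectively tail) is nulled and
flagged, keeping the pec — the identity anchor — intact. The filter is
idempotent.

**Jump detection.** Per body point, speed is displacement from the last valid
position divided by the frame gap. A fish "jumps" when at least two scored
points all exceed `jump_speed_max_cm`. Both fish jumping simultaneously is
the signature of an identity swap (`ID_SWAP`; both skeletons nulled); one
jumping fish is a `FISH_JUMP`; an isolated jumping point is a `POINT_JUMP`
(typical of body-part misidentification during close contact). References
never advance onto removed data, so a one-frame teleport produces exactly one
flagged frame. The speed bound is not prescribed anywhere upstream; the
default is 2.5 cm/frame — one body length per frame, i.e. 350 cm/s at 140 Hz,
several times burst-swim speed (~50–75 cm/s) yet far below the apparent
displacement when two fish exchange labels at typical separations. It is a
configuration value, never hard-coded, and the sharp `>` comparison means
artifacts whose per-frame speed lands exactly on the bound are kept; the
synthetic injector uses 8 cm teleports so that injected events stay
unambiguous even when a short dropout gap divides the displacement over
several frames.

**Gap closing and smoothing.** Per fish and scalar coordinate, interior runs
of missing values up to 7 frames long are filled by linear interpolation
(`INTERPOLATED` flag; gaps touching a sequence boundary are never filled),
then each contiguous valid segment of at least 9 frames is smoothed with a
second-order Savitzky–Golay filter, window 9 (shorter segments pass through
unsmoothed). The order-2 filter reproduces polynomials up to degree 2
exactly, so interpolated linear stretches are not distorted; its impulse
response has support of exactly one window. Gap counting is per coordinate —
the most permissive reading consistent with point-wise missingness.

`coverage_summary()` reports full frames (all three points, both fish),
empty frames (no point for either fish), and per-flag attrition counts.

## Gaze asymmetry

A fish's heading is the pec-to-head vector; its gaze angle toward the
partner is the angle between that heading and the vector from its own head
to the partner's head, in `[0°, 180°]`. The geometry is 3D by default with a
horizontal-projection mode available — neither the plane of measurement nor
the target reference point is constrained upstream, and head-to-head is the
symmetric choice consistent with the head-to-head distance series.

Over an analysis window (default 2 minutes, non-overlapping), with
`N_1→2` and `N_2→1` the frames in which fish 1 (respectively 2) is oriented
toward the other within the ±20° cone and `N_total` the frames in the window
with both gaze angles computable:

$$A_{\mathrm{gaze}} = \frac{|N_{1\to2} - N_{2\to1}|}{N_{\mathrm{total}}}$$

`A_gaze` is 0 for perfectly mutual engagement and 1 when only one fish ever
orients toward the other — the dominance signature. Defining `N_total` over
computable frames (rather than all frames) keeps the statistic invariant to
missing-data density; the two definitions coincide on complete windows.
Display smoothing of the asymmetry series is presentation only and not part
of the statistic. The joint 2D histogram of `(θ_{1→2}, θ_{2→1})` uses 36 × 36
bins over `[0°, 180°]` and transposes under fish relabeling.

## The synthetic generator

`simulate_dyad()` produces smoothed correlated-random-walk kinematics with
reflective walls inside the 25 × 25 × 25 cm cage at 140 Hz: velocity is an
AR(1) process (defaults `speed_alpha = 0.96`, `speed_sigma = 0.012` cm/frame,
giving cruising speeds of a few cm/s), and the heading relaxes toward the
swim direction rather than following it instantaneously — fish turn, they do
not flip — which keeps tail displacements physical when the velocity passes
through zero. The skeleton is rigid: head and tail at 0.9 cm and 1.6 cm from
the pec along the heading (a 2.5 cm fish). In pursuit mode, fish 1 follows
fish 2 at a 2–4 cm standoff from a configurable switch frame on, with its
body axis held on the partner's head plus small angular noise — a minimal
dominance-like regime that produces near-zero gaze asymmetry before the
switch and high asymmetry after it.

`render_detections()` projects the truth through synthetic cameras
(~36 px/cm, so a fish spans ~90 px) and applies, independently switchable:
Gaussian pixel noise (default 0.5 px), per-point dropouts (2%), head/tail
confusions (0.5%), per-frame scrambling of detection order, centroid noise
(2 px — the centroid is not the pec), and centroid label swaps (0.1%). Every
corruption is written to an injection log that tests use as the oracle.
`corrupt_tracks()` injects the same artifact classes directly at track level
for isolated QC testing. All outputs are bit-reproducible given the seed.

The synthetic cameras are exact quadratics per image coordinate in the single
world coordinate that the view images along that axis, with *distinct*
quadratic coefficients for the two views sharing each world axis — this makes
the world coordinates exactly affine in the image coordinates, so both
3D-mapping functions are exactly representable at degree 2 and parameter
recovery is exact. One limitation is intrinsic and worth stating: no camera
family with genuinely nonlinear per-axis response makes the *view maps*
exactly polynomial in both directions (the target's pixel response would have
to be a polynomial of the source's, and vice versa, forcing both affine), so
under the default cameras the degree-3 view maps carry a representability
floor of order 1e-5 px — negligible against the 10 px registration threshold,
and zero for the affine camera member used in exactness tests. An optional
`mismatch` mode adds cubic terms to produce realistic nonzero calibration
residuals.

What the generator does *not* emulate: occlusion geometry (dropouts are
independent, not contact-driven), detector confidence scores, refraction
model error (beyond the `mismatch` mode), and real behavioral structure
(bouts, thigmotaxis, fights). Passing tests on synthetic data therefore
demonstrates correctness of the algorithms under the stated corruption
models, not detector performance on real video.

## Problem sizes and determinism

The validation suite exercises the pipeline at desk scale, chosen so each
property is measured with adequate statistics: identity recovery over 10,000
rendered frames, QC rate recovery over 50,000 track frames (binomial 95%
intervals), pursuit asymmetry over 84,000 frames (five full 2-minute windows
at 140 Hz), and threshold boundaries by 40-step bisection sweeps. Every
stochastic quantity derives from an explicit seed; generator outputs are
byte-identical across runs.

## Known limitations

* Dyads only: the candidate enumeration generalizes to more animals but is
  deliberately scoped to two, matching the two-fish recording design.
* Close-contact frames in which the centroid tracker reports a single merged
  blob have no principled identity resolution here; they fall through to the
  jump filters, mirroring the upstream tools' behavior.
* The anatomy filter cannot tell which endpoint of an overlong segment is
  wrong; nulling the distal point is a convention, not an inference.
* Long gaps are left missing by design; model-based imputation is an
  application built on top of such data, not part of this pipeline.
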