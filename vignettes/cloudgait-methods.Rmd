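---
title: "Measuring locomotion from photogrammetric point-cloud sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring locomotion from photogrammetric point-cloud sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudgait)
```

## The measurement problem

Multi-camera photogrammetry turns each set of synchronised video frames
into a dense 3D point cloud of the scene. The reconstruction is faithful
up to a similarity: it has an arbitrary origin, an arbitrary orientation,
and an arbitrary global scale, because nothing in the images fixes metric
units. Before anything biological can be measured, three things must
happen:

1. **Orientation.** A feature known to be vertical (a pole, a wall edge)
   is fitted with a total-least-squares line and rotated onto +Z; a
   feature along the direction of locomotion is then fitted and rotated
   about +Z onto +X. The frame is right-handed, so +Y points to the left
   of an animal travelling along +X.
2. **Scale.** The clouds are undistorted, so one uniform factor suffices.
   Either a known in-scene length gives `s = L / ‖p₁ − p₂‖`, or — the
   field-friendly option — the tape-measured spacings of the cameras are
   compared with the optical centres recovered by bundle adjustment:
   `s = mean(physical) / mean(adjacent centre distances)`. The ratio of
   means (not the mean of ratios) matches calibrating with the *mean*
   camera separation. Optical centres satisfy `R c + t = 0` and are
   validated against an independent linear solve to 1e−9.
3. **Measurement.** Virtual markers are placed over presumed joint
   centres and tracked across frames; marker series feed velocity, angle
   and gait analyses.

All three stages are deterministic functions of declared inputs
(selections, measured lengths, config), so a measurement session is a
script, not a mouse log.

## Conventions and key parameters

* **Frame rates are exact rationals** (e.g. 30000/1001), so timestamps do
  not drift over long clips; presets `"30p"` and `"60p"` name the NTSC
  rates.
* **Line/plane fits** use the principal axes of the centred selection.
  Sign conventions: a line's direction dots non-negatively with
  (last − first selected point); near-equal principal values raise an
  `ambiguous_fit_warning` and keep the decomposition's lowest-index axis.
* **Sign hints in orientation.** A fitted pole direction is
  sign-ambiguous, and a static travel feature (a support rope) carries no
  motion direction. `orient_cloud` therefore accepts `up_hint` and
  `forward_hint` vectors — the operator's rough knowledge of "which way is
  up / which way it walked", expressed in cloud coordinates. Absent
  hints, the fit-sign convention decides, which can flip the scene; the
  hints are recommended for automated runs.
* **Projected segment angles.** With segment vector `u = b − a`:
  `θ_X = atan2(u_y, u_z)`, `θ_Y = atan2(u_x, u_z)`,
  `θ_Z = atan2(u_y, u_x)`, in degrees, each flagged undefined when the
  in-plane component is below 1e−9·‖u‖. These argument orders are this
  package's declared conventions (plots in the field rarely define
  signs); they are pinned by tests against a brute-force projection
  oracle and by rotation-consistency properties.
* **Velocity estimators.** Three are provided because they fail
  differently: interpolating/smoothing cubic splines differentiated
  analytically (smoothing 0 uses Forsythe–Malcolm–Moler end conditions,
  exact for cubic polynomials; otherwise `smooth.spline` with the
  smoothing level chosen by generalised cross-validation, the default
  since no principled fixed value exists); central finite differences
  (exact for quadratics); and OLS regression of position on time for
  absolute mean velocities, which uses valid samples only — gaps are
  never interpolated for regression.
* **Filtering.** The Butterworth low-pass is designed by bilinear
  transform with cutoff prewarping (via `signal::butter`) and applied
  forward-then-backward, giving zero phase and the squared response
  `|H|² = 1/(1 + (f/f_c)^(2p))` for `p` poles (defaults: 4 poles, 2 Hz).
  Edge handling: odd reflective padding (default three times the
  `fs/f_c` settling estimate) plus steady-state initialisation, so DC
  passes to within 1e−9. Interior gaps of at most `max_gap = 5` samples
  are linearly interpolated before filtering; longer gaps are an error
  that names the samples, because silently bridging a long reconstruction
  dropout would manufacture data.
* **Digitising.** The marker estimator is the centroid of cloud points in
  a search sphere — the simplest defensible reading of "place a virtual
  marker on the skin"; a placement needs at least `min_points = 5` points,
  otherwise the frame is flagged missing. Tracking carries the last
  accepted position forward as the next search centre. The radius should
  match the landmark's surface patch *and* exceed the subject's
  inter-frame displacement (speed / fps): ~0.08 m suits a walking primate
  at 60 fps, while a 4.7 m/s bird at 30/1.001 fps moves ~0.16 m per frame
  and needs ~0.25 m. Too large a radius swallows neighbouring segments
  whose membership varies with pose and imprints a periodic centroid
  bias.
* **Stance detection.** On a treadmill the stance foot rides the belt, so
  stance is "constant positive X velocity": the plateau `p` is the median
  of positive-velocity samples, and stance is any run with
  `|v − p| ≤ β·|p|` (β = 0.25). Overground, stance is
  `|v| ≤ γ·q₉₅(|v|)` (γ = 0.15). Runs shorter than `min_duration` are
  dropped; runs closer than `min_gap` merge. Intervals are half-open so
  stance and swing tile the span exactly. Because a zero-phase low-pass
  smears the stance/swing step symmetrically about the true event, the
  band is entered a fraction of the filter rise time late on each side;
  in treadmill mode the boundaries are therefore refined to the
  half-plateau crossing (`refine_boundaries = TRUE`), which is centred on
  the event and is a no-op on unfiltered square waves. For event
  detection we filter at ~6× the stride frequency (6 Hz by default in the
  pipeline); a 2 Hz cutoff is appropriate for displaying smooth
  trajectories from noisy manual digitising but rounds gait transients
  off.

## The synthetic scenes

The generator is marker-trajectory-first: joint paths are analytic
functions of time (so ground truth is exact by construction), body
segments are rendered as point scatter around the joint-to-joint lines,
and artefacts are layered on top. It emulates what dense reconstruction
actually produces:

* isotropic Gaussian noise on every point (σ defaults: 5 mm for the
  bright laboratory treadmill scene, 10 mm for the 20–30 m outdoor
  scenes);
* dropout as a **contiguous angular sector** of each segment's surface,
  not i.i.d. thinning — textureless fur patches vanish as patches, which
  is precisely what stresses the missing-marker pathway;
* a static textured background (scatter, an exactly vertical pole, an
  exactly +X rail) — reconstruction thrives on static texture, and the
  pole/rail double as the orientation features;
* one global random similarity transform per sequence into
  "reconstruction units" (cameras are static; per-frame transforms are
  deliberately out of scope), plus a matching Bundler rig whose adjacent
  centre separations are exact by construction.

The walker model: the hip translates at `V` (overground) or holds
station (treadmill); each foot alternates stance (planted, or riding the
belt at +V) and swing (cosine advance of one stride length `V/f`,
sinusoidal lift and lateral deviation, the lateral amplitude
configurable above the lift to reproduce abduction-dominated clearance);
feet are half a stride out of phase; the knee comes from two-link inverse
kinematics, and geometrically impossible stride/leg combinations are
rejected at generation. The flyer model: a straight climbing path at a
configurable heading with sinusoidally flapping wingtips. Scenario
presets (`treadmill_macaque`, `rope_chimp`, `plan_group`, `crow`) carry
each study set-up's camera spacing, distance, frame rate and speeds
(0.85 m/s walk; 4.74 m/s ground speed and 0.82 m/s climb; 0.35 m / 2 m /
1.7 m camera spacings). Where a set-up's parameter is not printed
anywhere (the treadmill walking speed, segment lengths), values typical
for the species and gait were fixed once: V = 0.7 m/s, f = 1 Hz,
thigh/shank 0.22/0.21 m for the macaque; 0.30/0.28 m for the chimpanzee.
`plan_group` models a single subject under the group-study camera
geometry — the generator is single-subject by design.

What the scenes do **not** emulate: perspective-dependent point density,
correlated (non-isotropic) reconstruction error, soft-tissue deformation,
frame-to-frame identity of surface points, or multiple interacting
subjects. Passing tests therefore demonstrate that the *measurement
chain* is correct and robust to noise, gaps and arbitrary similarity
transforms — not that any particular biological result would survive
real-world reconstruction pathologies.

## Numerical choices and degenerate inputs

* Rotations are validated to orthonormality (1e−9 for constructed
  transforms, 1e−6 for parsed camera poses, which are flagged suspect
  with a warning rather than rejected).
* The antiparallel case of "rotate v onto +Z" is a declared 180° rotation
  about +X.
* Coincident points, collinear plane selections, purely vertical travel
  directions, stationary realignment references and all-zero treadmill
  velocities raise classed errors (`degenerate_fit_error`,
  `no_plateau_error`, …) rather than returning garbage.
* PLY: big-endian files are rejected loudly; both `red/green/blue` and
  `diffuse_*` colour namings parse onto one field; ASCII output carries 9
  significant digits, binary output IEEE 4-byte floats (bit-exact round
  trips); truncated payloads report expected vs actual byte counts.
* Marker XML carries 17 significant digits (doubles round-trip exactly)
  and a schema version attribute checked on read.
* Frame numbers are the last digit run in the file stem, overridable by
  regex; duplicate frame numbers are an error, gaps are recorded.

## Problem sizes

The bundled tests and the acceptance script run the full chain at
deliberately modest sizes — 8–10 s clips (240–480 frames) with ~500–900
points per frame, 10 random seeds per recovery claim, 10⁵-point clouds
for I/O round-trips, 10⁴ random segments against the angle oracle. These
sizes were chosen so the whole suite re-runs in a few minutes while
keeping every statistical tolerance (3% on mean velocities, 0.05 on duty
factor, 2 frames on stance boundaries, 0.5° on recovered headings)
comfortably resolvable above estimator noise.

## Known limitations

* Carry-forward tracking can lose a marker whose per-frame displacement
  exceeds the search radius (fast flight at low frame rates); the remedy
  is a wider radius, at the price of the centroid bias discussed above.
  Predictive (velocity-extrapolated) search centres are an obvious
  extension point.
* The centroid estimator is biased toward whatever else the sphere
  contains; on segment-end landmarks this bias is roughly constant in the
  body frame and cancels in velocities and angles, but absolute marker
  positions carry it.
* Orientation accuracy is bounded by the verticality of the chosen
  feature; the package measures fit residuals but cannot know the
  feature's true inclination.
* The interactive digitising workflow this package replaces allowed the
  operator to adapt to each frame; the declarative replacement trades
  that judgement for reproducibility.
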