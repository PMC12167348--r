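---
title: "Methods: simulating marker-based AR navigation for endoscopic surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating marker-based AR navigation for endoscopic surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In endoscopic pituitary (skull-base) surgery the anatomy of interest is
hidden behind the nasal corridor, and navigation systems project
pre-operative CT anatomy into the endoscope video as an augmented-reality
(AR) overlay. The clinical standard tracks the endoscope with an infrared
(IR) stereo camera placed a couple of metres away, observing
retro-reflective bodies on the scope and on a patient-mounted clamp. An
alternative design mounts a small optical tracking camera directly on the
endoscope and tracks a printed fiducial board fixed to the patient's head:
the tracking baseline shrinks from metres to decimetres, and a single
patient reference replaces two tracked bodies.

`endonav` rebuilds both systems in simulation, on a synthetic phantom with
known ground truth, so that the complete error chain — intrinsic and
extrinsic calibration, patient-to-image registration, frame-by-frame
tracking, and the final overlay — can be measured, decomposed, and compared
between the two designs.

## Transform chains

All poses are rigid transforms $T = (R, t)$ acting on row-per-point
millimetre coordinates as $x \mapsto Rx + t$. Frame names follow the
`a_from_b` convention: `a_from_b` maps coordinates expressed in frame `b`
to frame `a`, so chains compose left to right, e.g.
`endocam_from_ct = endocam_from_world %o% world_from_ct`.

**On-board (marker-based) system.** One persistent registration
`board_from_ct` anchors the CT to the fiducial board. Each video frame
contributes the tracked board pose, and the overlay chain is

```
endocam_from_ct(t) = endo_from_trackcam . trackcam_from_board(t) . board_from_ct
```

with `endo_from_trackcam` a fixed extrinsic calibration. The registration
itself is automatic: the tracking camera's depth stream is back-projected
to a point cloud of the phantom's face, which is aligned to the CT surface
by robust point-to-plane ICP starting from an approximate prior
orientation, and the result is folded into the board reference via the
simultaneously observed board pose:

```
board_from_ct = inv(trackcam_from_board(t_reg)) . trackcam_from_ct(t_reg)
```

**IR-tracked comparator.** Two tracked bodies and a pointer-based
registration:

```
endocam_from_ct(t) = endocam_from_endoref . inv(tracker_from_endoref(t))
                     . tracker_from_patientref(t) . patientref_from_ct
```

where `patientref_from_ct` comes from Procrustes (Arun) alignment of seven
base fiducials digitized with a tracked pointer, and `endocam_from_endoref`
(the hand-eye) is treated as externally calibrated: the simulation supplies
ground truth plus an injected error of configurable magnitude, because a
bench system would obtain it from vendor software.

## Robust surface registration

The registration engine is iterative closest point with a point-to-plane
metric, a hard correspondence gate at 1 mm, and a Tukey biweight kernel of
scale $k = 0.1$:

$$ w(r) = \left(1 - (r/k)^2\right)^2 \;\; \text{for } |r| \le k, \quad 0
   \text{ otherwise.} $$

Three numerical decisions deserve explanation.

**Target representation.** The depth cloud (source) is registered onto the
CT *mesh* (target) with exact closest-point-on-triangle correspondences and
face normals, rather than onto a sampled point cloud of the CT. With a
sampled target, the point-to-plane residual of a perfectly aligned cloud is
not zero: a surface point lying between samples sits below the nearest
sample's tangent plane by $\approx \kappa d^2/2$ (curvature $\kappa$,
sample spacing $d$), a systematic bias of order $10^{-3}$ mm at our
sampling density that would contaminate every downstream accuracy number.
With the mesh target the residual vanishes identically at the true pose, so
the noiseless pipeline closes to machine precision and every reported error
is attributable to an injected noise source. The registration is run in the
CT frame and inverted for the chain; generic cloud-to-cloud ICP (with
PCA-estimated, viewpoint-oriented target normals) is also provided.

**Kernel scale and unit.** The scale is configured as $k = 0.1$ mm and the
configuration requires an explicit unit declaration (`k_unit = "mm"`),
because the number is quoted unitless in the source system description
while the correspondence gate is quoted in millimetres; a metre reading
(100 mm) would disable the kernel entirely inside the 1 mm gate. Both
readings are runnable (`k_mm` is free), the default documents the choice,
and the limit $k \to \infty$ is verified to reproduce plain least-squares
ICP. Under the default depth noise (0.5 mm) the 0.1 mm kernel uses roughly
the central fifth of the residual distribution — statistically inefficient
but unbiased for symmetric noise, and it is what the printed number says.

**Graduated annealing.** Taken literally, a 1 mm gate and 0.1 mm kernel
reject every correspondence when the initial alignment is off by the
realistic prior error (here 5 deg / 10 mm, and the basin requirement is
15 deg / 20 mm). The solver therefore anneals: gate and kernel are widened
by a multiplier $\mu_0$ set to three times the 90th percentile of the
initial correspondence distances over the gate (point-to-surface distances
understate pose error because tangential sliding is invisible to them,
hence the factor), the kernel is held at the current gate width while
$\mu > 1$, each scale is iterated until its cost stalls (1% relative), and
$\mu$ decays geometrically (factor 0.6) to 1. Convergence is only declared
at the final scale — exactly the published gate and kernel — when the
update is numerically zero or the best final-scale cost has not improved by
the relative tolerance (1e-8) for five consecutive iterations; the
five-iteration patience absorbs the cost churn caused by correspondence
membership changes under noise. Iteration cap: 50 by default, 100 in the
experiment configuration.

## Calibration

**Intrinsics** are calibrated from planar views of a 5x9 board with 20 mm
squares: DLT homographies (Hartley-normalized) give closed-form intrinsics
through the image-of-the-absolute-conic constraints, followed by
Levenberg-Marquardt refinement of intrinsics, five Brown-Conrady distortion
coefficients and per-view poses on pixel reprojection error (skew held at
zero; numeric Jacobians — at 69 parameters and 640 residuals there is
nothing to be gained from analytic ones). Degenerate view sets are detected
from the conditioning of the constraint system.

**Planar board poses** come from the homography of the undistorted
normalized coordinates, orthonormalized by polar projection, sign-chosen so
the board lies in front of the camera, and LM-refined; the refined pose is
only accepted if it does not increase the reprojection RMS.

**The endoscope-to-tracking-camera extrinsic** is estimated from frames
where both cameras see the same board: each frame gives
`E_i = endoscope_from_board_i . inv(trackingcam_from_board_i)`, and frames
are fused by chordal rotation averaging (orthogonal projection of the mean
rotation matrix, which is the Frobenius-optimal average and exactly
orthonormal by construction) with arithmetic mean translation. Per-frame
residuals against the average are reported; an optional residual-gated
re-average (drop frames beyond 3x the median residual, once) is off by
default. The source system says only that the relative transform is
computed from the two estimated poses; multi-frame fusion by chordal
averaging is this package's choice — deterministic, order-invariant, and
optimal for small isotropic rotation noise.

## The projected-TRE metric

Accuracy is scored as projected target registration error: for each
spherical target, the true chain and the estimated chain each project the
target into the endoscope image, both pixels are undistorted and
back-projected onto the plane perpendicular to the optical axis at the
target's *true* camera-frame depth, and the error is the Euclidean distance
in that plane (mm). This is the depth-aware conversion of an image offset
and reduces to the intuition $e = z\,\Delta_{px}/f$, verified against that
closed form; raw pixel distances are carried alongside. The metric is
invariant under a change of CT-frame gauge applied to both chains, and the
conversion choice matters because the published evaluation reports
millimetres without stating its pixel-to-mm convention — both conversions
are therefore reported.

## The synthetic world

The phantom generator emulates a surgical training head: a half-ellipsoid
(half-axes 90/70/110 mm) with a Gaussian nose ridge (12 mm amplitude),
closed by a base disk; a 5x5 grid of spherical targets at exactly 10 mm
pitch in an interior plane 40 mm above the base; seven fiducials on the
base perimeter; a fiducial board mounted on the holder beside the head. CT
acquisition and segmentation are modeled as a vertex-jittered copy of the
true surface (0.1 mm per-axis default). A re-meshing knob exists but
defaults to the same triangulation: coarser re-meshing introduces a
faceting error (~0.02 mm chord sagitta at default resolution) that is a
property of the mesh representation, not of any sensor, and it would mask
the noiseless-closure diagnostic that validates the whole pipeline.

Sensor and noise defaults, chosen once as realistic desk-scale values and
not revisited:

| parameter | default | rationale |
|---|---|---|
| endoscope camera | 1920x1080, f = 1100 px, k1 = -0.15, k2 = 0.03 | wide-angle endoscope with mild barrel distortion |
| tracking camera (board stream) | 1920x1080, f = 1380 px | depth-camera colour stream, factory rectified |
| depth stream | 212x120, f = 155 px | half-resolution depth render (runtime scale-down) |
| corner pixel noise | 0.5 px | typical sub-pixel corner detector |
| depth noise / dropout | 0.5 mm / 5% | stereo depth camera at ~0.3 m |
| tracker noise | 0.35 mm RMS, 0.1 deg mean abs | IR tracker at ~2 m |
| pointer tip noise | 0.3 mm per axis | tracked stylus digitization |
| hand-eye injected error | 0.15 deg / 0.5 mm | residual external calibration error |
| registration prior offset | 5 deg / 10 mm | coarse "face the camera" prior |
| geometry | board ~0.32 m from tracking camera, tracker ~2 m, endoscope ~0.22 m from targets | the stated working distances |
| calibration frames | 20 | unstated in the source; a round bench-realistic count |
| tracking board / calibration board | 6x4 / 15 mm, 5x9 / 20 mm | tracked reference unstated, calibration board as published |

Noise conventions are defined the way they are audited: tracker rotation
noise is the *mean absolute* perturbation angle (half-normal draw about a
random axis), tracker translation noise is the RMS of the displacement
norm, corner and pointer noises are per-component Gaussian sd. Body-pose
noise composes on the body side, so rotational noise pivots about the body,
not the tracker. One master seed fans out to per-stage child seeds through
a documented hash (`child_seed`), making every stage re-runnable in
isolation and every observation a pure function of (inputs, seed).

What the generator does **not** emulate: photorealistic imagery and real
marker decoding (detections are noisy 2D points), soft-tissue deformation,
intra-operative anatomy change, multi-view depth fusion, IR stray-marker
artifacts, and pointer pivot calibration. A green comparison therefore
establishes that the *geometric* error propagation favours the on-board
design under the stated noise model — it does not reproduce the absolute
published accuracies, which depend on hardware noise characteristics that
were never reported. For the same reason the experiment reproduces the
published *ordering* claim (the on-board system is more accurate because
its camera is near the reference), not the numbers 1.1 mm / 2.4 mm.

## Sensitivity experiments

`run_comparison_experiment()` repeats the full pipeline per seeded
repetition and aggregates per-system mean TRE. The acceptance suite checks,
besides noiseless closure and the ordering over 100 repetitions, that TRE
is non-decreasing in each individual noise source; those sweeps isolate one
source at a time against an otherwise noiseless pipeline (the sharpest
version of "all else fixed") with 15 repetitions per level for the
pipeline-heavy on-board sweeps and 50 for the cheap IR sweeps.

## Known limitations

* Brute-force correspondence search (C++): right for 10^3-10^4 points, not
  for dense clouds; there is no spatial index.
* Closest-point queries search the two-ring of the nearest vertex — exact
  for well-shaped meshes like the generator's, not for pathological
  triangulations.
* The planar-pose two-fold ambiguity is resolved by the positive-depth
  constraint plus refinement; at extreme grazing angles with tiny boards a
  flip is still possible (it does not occur at the configured geometry).
* `pose_error` uses the atan2 angle form, exact for small angles; axis
  extraction near 180 deg is ill-conditioned (the angle itself is fine).
* The IR hand-eye is injected, not estimated; comparing hand-eye
  *algorithms* is out of scope.
* A single static evaluation viewpoint per repetition mirrors the
  stationary-phantom protocol; a pose sweep would need scene-config
  variants.
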