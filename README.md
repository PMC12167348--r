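# endonav

Simulation toolkit for **marker-based augmented-reality (AR) navigation in
endoscopic skull-base surgery**, and for its head-to-head comparison with
the conventional infrared(IR)-tracked endoscope.

In image-guided pituitary surgery, pre-operative CT anatomy is overlaid on
the live endoscope image through a chain of estimated rigid transforms.
`endonav` implements both competing designs of that chain as testable
code on a synthetic phantom with known ground truth:

* **On-board system** — a tracking camera rigidly mounted on the endoscope
  observes a printed fiducial board fixed to the patient:

  `endocam_from_ct(t) = endo_from_trackcam ∘ trackcam_from_board(t) ∘ board_from_ct`

  The persistent registration `board_from_ct` is obtained *automatically*:
  the tracking camera's depth stream is back-projected to a face point
  cloud, aligned to the segmented CT surface by robust point-to-plane ICP
  (Tukey biweight, scale `k = 0.1` mm, 1 mm correspondence gate, graduated
  annealing from a coarse prior), and folded into the simultaneously
  observed board pose. The fixed extrinsic `endo_from_trackcam` comes from
  paired board poses seen by both cameras, fused by chordal rotation
  averaging.

* **IR-tracked comparator** — an IR tracker ~2 m away observes reference
  bodies on the scope and the head clamp; registration is closed-form
  Procrustes (Arun/SVD) alignment of seven pointer-digitized fiducials:

  `endocam_from_ct(t) = endocam_from_endoref ∘ inv(tracker_from_endoref(t)) ∘ tracker_from_patientref(t) ∘ patientref_from_ct`

Accuracy is scored as **projected target registration error (TRE)**: each
target of a 1 cm grid inside the phantom is projected through the true and
the estimated chain, and the image offset is converted to millimetres on
the plane at the target's true depth (`e = z·Δpx/f`). Everything —
phantom, CT model, depth maps, board detections, tracker frames, pointer
samples — is generated by a seeded synthetic-phantom module, so every
stage's error is measurable against ground truth.

Also included: Zhang planar intrinsic calibration (closed form +
Levenberg–Marquardt refinement), homography-based planar board pose with
occlusion tolerance, pinhole/Brown–Conrady camera model, depth-map
back-projection, plain-text PLY/STL/CSV/JSON/YAML interchange, and a CLI
(`exec/endonav`) with `simulate / calibrate / register / track / evaluate /
compare` subcommands.

## Worked example

```r
library(endonav)

cfg <- experiment_config()            # default noise model and geometry
res <- run_single_repetition(cfg, seed = 7L)
print(res$ours)
print(res$ir)
print(res$ours_diag$registration$icp_result)
```

```
<tre_report 'ours'> projected TRE 1.305 (+/- 0.493) mm over 25 targets
<tre_report 'ir'> projected TRE 2.011 (+/- 0.056) mm over 25 targets
<registration_result> converged after 30 iterations, cost 5.11, 826 inliers, RMS 0.05662 mm
```

One repetition simulates both systems end to end on the same phantom: the
on-board system overlays the 25-target grid with 1.3 mm mean error here,
the IR chain with 2.0 mm; the ICP line shows the automatic surface
registration that produced `board_from_ct` (inlier point-to-plane RMS
0.06 mm against the jittered CT model). Averaging over repetitions:

```r
cmp <- run_comparison_experiment(cfg, n_repetitions = 20L, seed = 1L)
print(cmp)
```

```
<comparison_result>
  ir    mean projected TRE 1.047 (+/- 0.413) mm over 20 repetitions
  ours  mean projected TRE 0.690 (+/- 0.306) mm over 20 repetitions
```

Under the default desk-scale noise model the on-board system is the more
accurate of the two — the tracking camera sits ~0.3 m from its reference
instead of ~2 m — which is the design claim this simulation reproduces.
Absolute bench accuracies depend on hardware noise that the simulation can
only parameterize, not measure; see `vignettes/endonav-methods.Rmd` for
the full noise model, the numerical choices inside the ICP and calibration
solvers, and what a green test does and does not establish.

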