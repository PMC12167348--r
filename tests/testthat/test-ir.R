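test_that("IR fiducial registration recovers truth and reports FRE", {
  s <- small_scene()
  ph <- s$scene$phantom
  fids <- phantom_fiducial_set(ph)
  pref_from_ct <- rt_invert(s$scene$rig$ct_from_patientref)

  clean <- sample_fiducials_with_pointer(ph, pref_from_ct, 0, seed = 1L)
  reg <- register_ir(fids, clean)
  expect_pose_close(reg$patientref_from_ct, pref_from_ct, 1e-9, 1e-9)
  expect_lt(reg$fre, 1e-9)

  # noisy sampling: finite errors, FRE bounded by the worst noise magnitude
  sam <- sample_fiducials_with_pointer(ph, pref_from_ct, 0.3, seed = 2L)
  noisy <- register_ir(fids, sam)
  expect_true(all(is.finite(pose_error(noisy$patientref_from_ct, pref_from_ct))))
  worst <- max(sqrt(rowSums((as.matrix(sam[, 2:4]) -
                               rt_apply(pref_from_ct,
                                        fids$points_ct))^2)))
  expect_lte(noisy$fre, worst)
  # cross-check FRE against a direct recomputation
  resid <- rt_apply(noisy$patientref_from_ct, fids$points_ct) -
    as.matrix(sam[, 2:4])
  expect_equal(noisy$fre, sqrt(mean(rowSums(resid^2))), tolerance = 1e-12)

  # six of seven fiducials: proceeds with a warning
  expect_warning(sub <- register_ir(fids, sam[1:6, ]), "6 of 7")
  expect_equal(sub$n_used, 6)
  expect_error(suppressWarnings(register_ir(fids, sam[1:2, ])),
               class = "endonav_invalid_fiducials")
  bad <- sam; bad$id <- bad$id + 100
  expect_error(register_ir(fids, bad), class = "endonav_invalid_fiducials")
})

test_that("the IR overlay chain reproduces ground truth when fed truth", {
  s <- small_scene()
  scene <- s$scene
  fr <- observe_tracker(scene$rig, scene$phantom, scene$endocam_from_world,
                        noise_config_zero(), frame = 1L, seed = 1L)
  out <- ir_overlay_chain(fr, scene$rig$endocam_from_endoref,
                          rt_invert(scene$rig$ct_from_patientref),
                          s$cfg$endo_intrinsics, scene$phantom$targets)
  expect_equal(out$status, "ok")
  truth_px <- project_points(s$cfg$endo_intrinsics, scene$endocam_from_ct,
                             scene$phantom$targets)$pixels
  expect_lt(max(abs(out$pixels - truth_px)), 1e-9)

  # invalid body: frame skipped with explicit status
  fr$valid["patientref"] <- FALSE
  out2 <- ir_overlay_chain(fr, scene$rig$endocam_from_endoref,
                           rt_invert(scene$rig$ct_from_patientref),
                           s$cfg$endo_intrinsics, scene$phantom$targets)
  expect_equal(out2$status, "skipped")
  expect_null(out2$pixels)
})

test_that("a small endoscope-body rotation shifts the overlay by theta x L", {
  s <- small_scene()
  scene <- s$scene
  fr <- observe_tracker(scene$rig, scene$phantom, scene$endocam_from_world,
                        noise_config_zero(), frame = 1L, seed = 1L)
  base <- ir_overlay_chain(fr, scene$rig$endocam_from_endoref,
                           rt_invert(scene$rig$ct_from_patientref),
                           s$cfg$endo_intrinsics, scene$phantom$targets)
  theta <- 0.1 * pi / 180
  fr2 <- fr
  fr2$tracker_from_endoref <- rt_compose(
    fr$tracker_from_endoref,
    rigid_transform(rotation_about("y", 0.1), c(0, 0, 0)))
  pert <- ir_overlay_chain(fr2, scene$rig$endocam_from_endoref,
                           rt_invert(scene$rig$ct_from_patientref),
                           s$cfg$endo_intrinsics, scene$phantom$targets)
  # displacement of the chain in 3D against the small-angle prediction:
  # the perturbation rotates camera-frame space about the axis through the
  # endoscope-reference body origin, so |dx| ~ theta * L_perp
  p0 <- rt_apply(base$endocam_from_ct, scene$phantom$targets)
  p1 <- rt_apply(pert$endocam_from_ct, scene$phantom$targets)
  shift <- sqrt(rowSums((p1 - p0)^2))
  he <- scene$rig$endocam_from_endoref
  axis_pt <- he$translation          # body origin in camera frame
  axis_dir <- he$rotation[, 2]       # perturbation axis (body y) in camera
  v <- sweep(p0, 2, axis_pt)
  perp <- v - outer(as.numeric(v %*% axis_dir), axis_dir)
  pred <- theta * sqrt(rowSums(perp^2))
  expect_equal(shift, pred, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("overlay error grows linearly with tracker angular noise", {
  s <- small_scene()
  scene <- s$scene
  mean_err <- function(sig) {
    noise <- noise_config(tracker_rot_sigma_deg = sig,
                          tracker_trans_sigma_mm = 0)
    mean(vapply(1:40, function(f) {
      fr <- observe_tracker(scene$rig, scene$phantom,
                            scene$endocam_from_world, noise, frame = f,
                            seed = 11L)
      out <- ir_overlay_chain(fr, scene$rig$endocam_from_endoref,
                              rt_invert(scene$rig$ct_from_patientref),
                              s$cfg$endo_intrinsics, scene$phantom$targets)
      projected_tre(scene$phantom$targets, scene$endocam_from_ct,
                    out$endocam_from_ct, s$cfg$endo_intrinsics)$mean_mm
    }, 0))
  }
  e1 <- mean_err(0.05)
  e2 <- mean_err(0.2)
  # linear scaling: quadrupling the noise about quadruples the error
  expect_equal(e2 / e1, 4, tolerance = 0.4)
})
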