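test_that("the marker-based overlay chain closes on ground truth", {
  s <- small_scene()
  scene <- s$scene
  trackcam_from_board <- rt_compose(scene$trackcam_from_world,
                                    scene$world_from_board)
  out <- our_overlay_chain(trackcam_from_board, scene$endo_from_trackcam,
                           rt_invert(scene$phantom$ct_from_board), s$cfg$endo_intrinsics,
                           scene$phantom$targets)
  expect_equal(out$status, "ok")
  truth_px <- project_points(s$cfg$endo_intrinsics, scene$endocam_from_ct,
                             scene$phantom$targets)$pixels
  expect_lt(max(abs(out$pixels - truth_px)), 1e-9)

  # lost board: explicit no-pose status (caller holds the previous pose)
  expect_equal(our_overlay_chain(NULL, scene$endo_from_trackcam,
                                 rt_invert(scene$phantom$ct_from_board),
                                 s$cfg$endo_intrinsics,
                                 scene$phantom$targets)$status, "no_pose")
})

test_that("a small board translation shifts pixels by fx * delta / z", {
  s <- small_scene()
  scene <- s$scene
  intr <- s$cfg$endo_intrinsics
  intr$dist <- rep(0, 5)  # first-order check without distortion
  trackcam_from_board <- rt_compose(scene$trackcam_from_world,
                                    scene$world_from_board)
  base <- our_overlay_chain(trackcam_from_board, scene$endo_from_trackcam,
                            rt_invert(scene$phantom$ct_from_board), intr,
                            scene$phantom$targets)
  delta <- 0.5  # mm along the tracking camera x axis
  shifted_pose <- rt_compose(rigid_transform(diag(3), c(delta, 0, 0)),
                             trackcam_from_board)
  pert <- our_overlay_chain(shifted_pose, scene$endo_from_trackcam,
                            rt_invert(scene$phantom$ct_from_board), intr,
                            scene$phantom$targets)
  # the endoscope sees the shift through the fixed extrinsic rotation; the
  # first-order pixel displacement is |fx * R delta / z|
  dvec <- as.numeric(scene$endo_from_trackcam$rotation %*% c(delta, 0, 0))
  z <- project_points(intr, base$endocam_from_ct, scene$phantom$targets)$depth
  pred <- intr$fx * sqrt(dvec[1]^2 + dvec[2]^2) / z
  got <- sqrt(rowSums((pert$pixels - base$pixels)^2))
  expect_equal(got, pred, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("projected TRE matches the closed form z * dpx / f", {
  intr <- test_intrinsics()
  targets <- rbind(c(0, 0, 0))
  z <- 250
  truth_chain <- rigid_transform(diag(3), c(0, 0, z))
  # camera-frame lateral shift produces a pure pixel offset
  delta <- 0.8
  est_chain <- rt_compose(rigid_transform(diag(3), c(delta, 0, 0)), truth_chain)
  rep1 <- projected_tre(targets, truth_chain, est_chain, intr)
  dpx <- rep1$pixel_error_px[1]
  expect_equal(rep1$per_target_mm[1], z * dpx / intr$fx, tolerance = 1e-6)
  expect_equal(rep1$per_target_mm[1], delta, tolerance = 1e-9)
})

test_that("a 1 mm in-plane shift of a 10 mm grid gives mean TRE 1 mm", {
  intr <- test_intrinsics()
  g <- expand.grid(x = seq(-20, 20, 10), y = seq(-20, 20, 10))
  targets <- cbind(g$x, g$y, 0)
  truth_chain <- rigid_transform(diag(3), c(0, 0, 300))
  est_chain <- rt_compose(rigid_transform(diag(3), c(1, 0, 0)), truth_chain)
  rep1 <- projected_tre(targets, truth_chain, est_chain, intr)
  expect_equal(rep1$mean_mm, 1, tolerance = 1e-6)
  expect_lt(rep1$sd_mm, 1e-6)
  expect_equal(rep1$n, 25)
})

test_that("projected TRE is invariant to a common CT-frame gauge change", {
  s <- small_scene()
  scene <- s$scene
  truth_chain <- scene$endocam_from_ct
  est_chain <- perturb_pose(truth_chain, 0.2, 0.5, seed = 5L)
  base <- projected_tre(scene$phantom$targets, truth_chain, est_chain,
                        s$cfg$endo_intrinsics)
  M <- random_pose(seed = 6, 30, 50)
  moved <- projected_tre(rt_apply(rt_invert(M), scene$phantom$targets),
                         rt_compose(truth_chain, M), rt_compose(est_chain, M),
                         s$cfg$endo_intrinsics)
  expect_equal(moved$per_target_mm, base$per_target_mm, tolerance = 1e-9)
})

test_that("TRE reports keep aggregates consistent with the per-target list", {
  errs <- c(0.2, 0.8, 1.3, 0.5)
  r <- tre_report(errs, system = "demo")
  expect_identical(r$mean_mm, mean(errs))
  expect_identical(r$sd_mm, sd(errs))
  expect_identical(r$n, 4L)
  expect_error(tre_report(c(0.1, -0.2)), class = "endonav_invalid_report")
  # degenerate chains: every target identical -> zero errors
  s <- small_scene()
  same <- projected_tre(s$scene$phantom$targets, s$scene$endocam_from_ct,
                        s$scene$endocam_from_ct, s$cfg$endo_intrinsics)
  expect_equal(max(same$per_target_mm), 0)
})
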