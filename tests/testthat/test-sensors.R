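test_that("depth rendering is exact on an analytic plane scene", {
  # a big square at z = 300 in front of the camera
  quad <- surface_mesh(rbind(c(-500, -500, 300), c(500, -500, 300),
                             c(500, 500, 300), c(-500, 500, 300)),
                       rbind(c(1, 2, 3), c(1, 3, 4)))
  intr <- camera_intrinsics(100, 100, 32, 24, 64, 48)
  dm <- render_depth(quad, rt_identity(), intr)
  vals <- dm$depth[dm$depth != 0]
  expect_gt(length(vals), 3000)
  expect_lt(max(abs(vals - 300)), 1e-9)
})

test_that("noiseless depth back-projects onto the face surface", {
  fc <- face_cloud(1500)
  mesh_cam <- surface_mesh(rt_apply(fc$scene$trackcam_from_ct,
                                    fc$scene$phantom$face$vertices),
                           fc$scene$phantom$face$faces)
  co <- endonav:::icp_correspond(fc$cloud$points, mesh_cam,
                                 endonav:::mesh_two_ring(mesh_cam))
  expect_lt(max(co$d), 1e-6)
})

test_that("depth noise and dropout follow their stated models", {
  s <- small_scene()
  noise <- noise_config(depth_sigma_mm = 0, depth_dropout = 0.3)
  dm0 <- render_depth(s$scene$phantom, s$scene$trackcam_from_world,
                      s$cfg$depth_intrinsics, noise_config_zero())
  n_valid <- sum(dm0$depth != 0)
  dm <- render_depth(s$scene$phantom, s$scene$trackcam_from_world,
                     s$cfg$depth_intrinsics, noise, seed = 5L)
  frac <- 1 - sum(dm$depth != 0) / n_valid
  expect_equal(frac, 0.3, tolerance = 0.03)

  noise2 <- noise_config(depth_sigma_mm = 0.5, depth_dropout = 0)
  dm2 <- render_depth(s$scene$phantom, s$scene$trackcam_from_world,
                      s$cfg$depth_intrinsics, noise2, seed = 6L)
  diffs <- (dm2$depth - dm0$depth)[dm0$depth != 0]
  expect_equal(sd(diffs), 0.5, tolerance = 0.02)

  # determinism
  dm3 <- render_depth(s$scene$phantom, s$scene$trackcam_from_world,
                      s$cfg$depth_intrinsics, noise2, seed = 6L)
  expect_identical(dm2$depth, dm3$depth)
})

test_that("board observation applies occlusion and pixel noise as stated", {
  s <- small_scene()
  board <- make_board(5, 9, 20)  # 32 points
  wfb <- endonav:::calib_board_pose(s$cfg, s$scene, 1, 3L)
  det0 <- observe_board(board, wfb, s$scene$trackcam_from_world,
                        s$cfg$track_intrinsics, noise_config_zero())
  # zero noise: detections equal exact projections
  pts <- rt_apply(wfb, cbind(board$points$x_mm, board$points$y_mm, 0))
  pr <- project_points(s$cfg$track_intrinsics, s$scene$trackcam_from_world, pts)
  expect_equal(det0$pixels, pr$pixels[pr$visible, , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)

  # occlusion 0.5 on a fully visible 32-point board: exactly 16 survive
  if (nrow(det0$pixels) == 32) {
    occl <- observe_board(board, wfb, s$scene$trackcam_from_world,
                          s$cfg$track_intrinsics,
                          noise_config(board_occlusion = 0.5,
                                       corner_px_sigma = 0), seed = 7L)
    expect_equal(length(occl$point_ids), 16)
  }

  # pixel-noise sd audit on one corner over many draws
  one <- make_board(2, 2, 10)
  us <- vapply(1:4000, function(s2) {
    d <- observe_board(one, wfb, s$scene$trackcam_from_world,
                       s$cfg$track_intrinsics,
                       noise_config(corner_px_sigma = 0.5), seed = s2)
    d$pixels[1, 1]
  }, 0)
  expect_equal(sd(us), 0.5, tolerance = 0.02)
})

test_that("tracker observation is exact when clean and audits its noise", {
  s <- small_scene()
  fr0 <- observe_tracker(s$scene$rig, s$scene$phantom,
                         s$scene$endocam_from_world, noise_config_zero(),
                         frame = 1L, seed = 1L)
  truth_pat <- rt_compose(s$scene$rig$tracker_from_world,
                          rt_compose(s$scene$phantom$world_from_ct,
                                     s$scene$rig$ct_from_patientref))
  expect_pose_close(fr0$tracker_from_patientref, truth_pat, 1e-9, 1e-9)

  # same (frame, seed) -> identical output
  fr0b <- observe_tracker(s$scene$rig, s$scene$phantom,
                          s$scene$endocam_from_world, noise_config_zero(),
                          frame = 1L, seed = 1L)
  expect_identical(fr0$tracker_from_patientref$rotation,
                   fr0b$tracker_from_patientref$rotation)

  # mean absolute rotation perturbation equals the configured 0.1 deg
  noise <- noise_config(tracker_rot_sigma_deg = 0.1,
                        tracker_trans_sigma_mm = 0)
  angs <- vapply(1:1000, function(f) {
    fr <- observe_tracker(s$scene$rig, s$scene$phantom,
                          s$scene$endocam_from_world, noise, frame = f,
                          seed = 2L)
    pose_error(fr$tracker_from_patientref, truth_pat)[["rotation_deg"]]
  }, 0)
  expect_equal(mean(angs), 0.1, tolerance = 0.1)
})

test_that("pointer sampling of fiducials is exact, seeded, and calibrated", {
  s <- small_scene()
  ph <- s$scene$phantom
  pref_from_ct <- rt_invert(s$scene$rig$ct_from_patientref)
  clean <- sample_fiducials_with_pointer(ph, pref_from_ct, 0, seed = 1L)
  truth <- rt_apply(pref_from_ct, cbind(ph$fiducials$x_mm, ph$fiducials$y_mm,
                                        ph$fiducials$z_mm))
  expect_equal(as.matrix(clean[, 2:4]), truth, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(sample_fiducials_with_pointer(ph, pref_from_ct, 0.3, seed = 2L),
                   sample_fiducials_with_pointer(ph, pref_from_ct, 0.3, seed = 2L))
  # per-axis sd audit over 1000 repetitions
  dev <- vapply(1:1000, function(s2) {
    sam <- sample_fiducials_with_pointer(ph, pref_from_ct, 0.3, seed = s2)
    sam$x_mm[1] - truth[1, 1]
  }, 0)
  expect_equal(sd(dev), 0.3, tolerance = 0.03)
})

test_that("tracker frames round-trip through the CSV log", {
  s <- small_scene()
  frames <- lapply(1:3, function(f)
    observe_tracker(s$scene$rig, s$scene$phantom, s$scene$endocam_from_world,
                    noise_config(), frame = f, seed = 9L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracker_csv(frames, path)
  back <- read_tracker_csv(path)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_pose_close(back[[i]]$tracker_from_patientref,
                      frames[[i]]$tracker_from_patientref, 1e-9, 1e-9)
    expect_pose_close(back[[i]]$tracker_from_endoref,
                      frames[[i]]$tracker_from_endoref, 1e-9, 1e-9)
  }
})

test_that("noise configurations validate and round-trip through YAML", {
  expect_error(noise_config(depth_dropout = 1.4), class = "endonav_invalid_config")
  expect_error(noise_config(corner_px_sigma = -1), class = "endonav_invalid_config")
  nc <- noise_config(corner_px_sigma = 0.7, seed = 42L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_noise_yaml(nc, path)
  expect_equal(read_noise_yaml(path), nc)
})
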