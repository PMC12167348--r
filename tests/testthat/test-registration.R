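test_that("normal estimation recovers plane and sphere normals", {
  g <- expand.grid(x = seq(-40, 40, 4), y = seq(-40, 40, 4))
  plane <- point_cloud(cbind(g$x, g$y, 0))
  est <- estimate_normals(plane, k_neighbors = 8, viewpoint = c(0, 0, 100))
  expect_lt(max(abs(est$normals - rep(c(0, 0, 1), each = nrow(g)))), 1e-6)

  # dense quasi-uniform (Fibonacci) sphere, viewpoint at centre:
  # normals antiparallel to radius
  n <- 4000
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  sph <- point_cloud(50 * dirs)
  est <- estimate_normals(sph, k_neighbors = 10, viewpoint = c(0, 0, 0))
  ang <- acos(pmin(1, -rowSums(est$normals * dirs))) * 180 / pi
  expect_lt(max(ang), 2)

  expect_error(estimate_normals(point_cloud(matrix(0, 2, 3)), k_neighbors = 3),
               class = "endonav_invalid_cloud")
})

test_that("Tukey weights satisfy the kernel contract", {
  k <- 0.1
  r <- seq(-2 * k, 2 * k, length.out = 10000)
  w <- tukey_weight(r, k)
  expect_equal(tukey_weight(0, k), 1)
  expect_equal(tukey_weight(c(-k, k), k), c(0, 0))
  expect_true(all(w[abs(r) > k] == 0))
  expect_true(all(w >= 0 & w <= 1))
  half <- tukey_weight(seq(0, k, length.out = 5000), k)
  expect_true(all(diff(half) <= 1e-12))
})

test_that("ICP is exact on an identical copy and recovers a displacement", {
  fc <- face_cloud(1500)
  src <- fc$cloud
  tgt <- estimate_normals(src, k_neighbors = 10)
  # identical clouds, identity start: one-iteration convergence at zero cost
  res <- icp_point_to_plane_robust(src, tgt, icp_config())
  expect_true(res$converged)
  expect_lte(res$cost, 1e-18)
  expect_pose_close(res$transform, rt_identity(), 1e-9, 1e-9)

  # known (5 deg, 5 mm) displacement, cloud-to-cloud
  truth <- perturb_pose(rt_identity(), 5, 5, seed = 40)
  moved <- point_cloud(rt_apply(rt_invert(truth), src$points))
  res <- icp_point_to_plane_robust(moved, tgt, icp_config())
  expect_pose_close(res$transform, truth, 1e-4, 1e-3)
})

test_that("robust ICP ignores gross outliers and matches the clean oracle", {
  fc <- face_cloud(2000)
  mesh <- fc$scene$phantom$face
  truth <- rt_invert(fc$scene$trackcam_from_ct)  # ct_from_camera
  pts <- fc$cloud$points
  n_out <- round(0.2 * nrow(pts))
  out_idx <- with_seed(41, sample.int(nrow(pts), n_out))
  # construct outliers in the CT frame (where the mesh lives) so the
  # off-surface guarantee holds at the registered pose, then map back
  corrupt <- rt_apply(rt_invert(truth),
                      make_off_surface_outliers(rt_apply(truth, pts), out_idx,
                                                mesh, seed = 42))
  init <- rt_compose(perturb_pose(rt_identity(), 15, 20, seed = 43), truth)

  robust <- icp_point_to_plane_robust(point_cloud(corrupt), mesh,
                                      icp_config(max_iterations = 100),
                                      init = init)
  expect_pose_close(robust$transform, truth, 0.1, 0.1)

  oracle <- icp_point_to_plane_robust(point_cloud(pts[-out_idx, ]), mesh,
                                      icp_config(loss = "none",
                                                 max_iterations = 100),
                                      init = init)
  expect_pose_close(robust$transform, oracle$transform, 0.05, 0.05)

  # every outlier ends up with zero influence (outside gate or kernel)
  moved <- rt_apply(robust$transform, corrupt[out_idx, , drop = FALSE])
  co <- endonav:::icp_correspond(moved, mesh, endonav:::mesh_two_ring(mesh))
  infl <- co$d <= 1  # inside the 1 mm gate
  r <- rowSums(co$n * (moved - co$q))
  w <- tukey_weight(r, 0.1)
  expect_true(all(!infl | w == 0))
})

test_that("robust ICP with k -> Inf equals least-squares ICP", {
  fc <- face_cloud(1200)
  mesh <- fc$scene$phantom$face
  # surface points in the CT frame, displaced by a known small offset
  pts_ct <- rt_apply(rt_invert(fc$scene$trackcam_from_ct), fc$cloud$points)
  offset <- perturb_pose(rt_identity(), 4, 4, seed = 44)
  src <- point_cloud(rt_apply(offset, pts_ct))
  a <- icp_point_to_plane_robust(src, mesh, icp_config(loss = "tukey",
                                                       k_mm = 1e9))
  b <- icp_point_to_plane_robust(src, mesh, icp_config(loss = "none"))
  expect_pose_close(a$transform, rt_invert(offset), 1e-4, 1e-3)
  expect_pose_close(a$transform, b$transform, 1e-6, 1e-6)
})

test_that("final robust cost never exceeds the initial cost", {
  fc <- face_cloud(1000)
  mesh <- fc$scene$phantom$face
  truth <- rt_invert(fc$scene$trackcam_from_ct)
  for (s in 1:5) {
    init <- rt_compose(perturb_pose(rt_identity(), 8, 10, seed = 50 + s), truth)
    res <- icp_point_to_plane_robust(fc$cloud, mesh,
                                     icp_config(max_iterations = 80),
                                     init = init)
    expect_lte(res$cost, res$initial_cost + 1e-12)
  }
})

test_that("initial_align_from_prior moves CT vertices and records the prior", {
  fc <- face_cloud(500)
  mesh <- fc$scene$phantom$face
  expect_equal(initial_align_from_prior(mesh, rt_identity())$points,
               mesh$vertices)
  prior <- random_pose(seed = 60, 10, 20)
  al <- initial_align_from_prior(mesh, prior)
  expect_equal(al$points, rt_apply(prior, mesh$vertices))
  expect_equal(attr(al, "prior"), prior)
})

test_that("registration from a prior recovers the exact pose on clean data", {
  fc <- face_cloud(2500)
  cfg <- fc$cfg
  scene <- fc$scene
  # prior equal to truth: immediate convergence
  reg <- register_depth_to_ct(fc$cloud, scene$phantom$face,
                              scene$trackcam_from_ct, cfg$icp)
  expect_pose_close(reg$camera_from_ct, scene$trackcam_from_ct, 1e-6, 1e-6)
  # (15 deg, 20 mm) prior offset: basin check
  prior <- perturb_pose(scene$trackcam_from_ct, 15, 20, seed = 71)
  reg <- register_depth_to_ct(fc$cloud, scene$phantom$face, prior, cfg$icp)
  expect_pose_close(reg$camera_from_ct, scene$trackcam_from_ct, 1e-4, 1e-3)
})

test_that("Procrustes registration is exact, optimal and guarded", {
  fid <- with_seed(80, matrix(runif(21, -80, 80), 7, 3))
  truth <- random_pose(seed = 81, 40, 60)
  target <- rt_apply(truth, fid)
  reg <- procrustes_register(fid, target)
  expect_pose_close(reg$transform, truth, 1e-9, 1e-9)
  expect_lt(reg$fre, 1e-9)

  # common rigid motion of both sets leaves the FRE unchanged
  noisy <- target + with_seed(82, matrix(rnorm(21, 0, 0.3), 7, 3))
  base <- procrustes_register(fid, noisy)
  common <- random_pose(seed = 83, 30, 40)
  moved <- procrustes_register(rt_apply(common, fid), rt_apply(common, noisy))
  expect_equal(moved$fre, base$fre, tolerance = 1e-9)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(procrustes_register(line, line), class = "endonav_degenerate")
  expect_error(procrustes_register(fid[1:2, ], target[1:2, ]),
               class = "endonav_degenerate")
})

test_that("compose_ct_to_reference closes the registration chain", {
  expect_pose_close(compose_ct_to_reference(rt_identity(), rt_identity()),
                    rt_identity(), 1e-12, 1e-12)
  s <- small_scene()$scene
  cam_from_ct <- s$trackcam_from_ct
  cam_from_board <- rt_compose(s$trackcam_from_world, s$world_from_board)
  b_from_ct <- compose_ct_to_reference(cam_from_ct, cam_from_board)
  expect_pose_close(b_from_ct, rt_invert(s$phantom$ct_from_board), 1e-9, 1e-9)
  # chain closure: board pose times registration reproduces camera_from_ct
  expect_pose_close(rt_compose(cam_from_board, b_from_ct), cam_from_ct,
                    1e-9, 1e-9)
})
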