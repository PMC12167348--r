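test_that("compose, invert and apply satisfy their algebra", {
  rz <- rigid_transform(rotation_about("z", 90), c(0, 0, 0))
  t1 <- rigid_transform(rotation_about("z", 90), c(1, 2, 3))

  # identity is neutral
  expect_equal(rt_compose(rt_identity(), t1), t1, tolerance = 1e-12)

  # T o inv(T) = identity
  round_trip <- rt_compose(t1, rt_invert(t1))
  expect_lt(max(abs(round_trip$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(round_trip$translation)), 1e-9)

  # (90 about z) o (90 about z) acts as 180 about z on basis vectors
  twice <- rt_compose(rz, rz)
  basis <- diag(3)
  expect_equal(rt_apply(twice, basis),
               rt_apply(rigid_transform(rotation_about("z", 180)), basis),
               tolerance = 1e-9)

  # pure translation inverts to its negation
  tr <- rigid_transform(diag(3), c(1, 2, 3))
  expect_equal(rt_invert(tr)$translation, c(-1, -2, -3))

  # 180 about z maps (1,0,0) to (-1,0,0)
  expect_equal(as.numeric(rt_apply(rigid_transform(rotation_about("z", 180)),
                                   c(1, 0, 0))),
               c(-1, 0, 0), tolerance = 1e-12)

  # identity leaves any cloud unchanged; N preserved
  pts <- matrix(rnorm(300), 100, 3)
  expect_identical(dim(rt_apply(rt_identity(), pts)), dim(pts))
  expect_equal(rt_apply(rt_identity(), pts), pts)
})

test_that("rigid transforms preserve pairwise distances", {
  pose <- random_pose(seed = 11, max_rotation_deg = 170, max_translation_mm = 80)
  pts <- with_seed(12, matrix(rnorm(300, sd = 50), 100, 3))
  moved <- rt_apply(pose, pts)
  expect_lt(max(abs(dist(pts) - dist(moved))), 1e-9)
})

test_that("invalid transforms and points are rejected", {
  expect_error(rigid_transform(matrix(1:9, 3, 3)), class = "endonav_invalid_transform")
  expect_error(rigid_transform(diag(3) * 2), class = "endonav_invalid_transform")
  expect_error(rigid_transform(diag(c(1, 1, -1))), class = "endonav_invalid_transform")
  expect_error(rt_apply(rt_identity(), matrix(c(1, 2, NA), 1, 3)), "non-finite")
})

test_that("pose_error measures relative rotation angle and translation norm", {
  t1 <- random_pose(seed = 1)
  expect_equal(unname(pose_error(t1, t1)), c(0, 0), tolerance = 1e-9)
  rx <- rigid_transform(rotation_about("x", 10))
  expect_equal(pose_error(rt_identity(), rx)[["rotation_deg"]], 10,
               tolerance = 1e-9)
  tr <- rigid_transform(diag(3), c(3, 4, 0))
  expect_equal(unname(pose_error(rt_identity(), tr)), c(0, 5), tolerance = 1e-12)
  # symmetry
  t2 <- random_pose(seed = 2)
  expect_equal(pose_error(t1, t2), pose_error(t2, t1), tolerance = 1e-9)
})

test_that("random_pose is deterministic and respects its bounds", {
  expect_equal(random_pose(5, 0, 0), rt_identity(), tolerance = 1e-12)
  expect_equal(random_pose(5, 30, 50), random_pose(5, 30, 50))
  for (s in 1:200) {
    p <- random_pose(s, 30, 50)
    pe <- pose_error(rt_identity(), p)
    expect_lte(pe[["rotation_deg"]], 30 + 1e-9)
    expect_lte(sqrt(sum(p$translation^2)), 50 + 1e-9)
  }
})

test_that("composition is associative and consistent with apply", {
  pts <- with_seed(4, matrix(rnorm(30, sd = 20), 10, 3))
  for (s in 1:20) {
    a <- random_pose(3 * s); b <- random_pose(3 * s + 1); c3 <- random_pose(3 * s + 2)
    lhs <- rt_compose(rt_compose(a, b), c3)
    rhs <- rt_compose(a, rt_compose(b, c3))
    expect_lt(max(abs(rt_to_matrix4(lhs) - rt_to_matrix4(rhs))), 1e-9)
    expect_lt(max(abs(rt_apply(rt_compose(a, b), pts) -
                        rt_apply(a, rt_apply(b, pts)))), 1e-9)
  }
})

test_that("rodrigues conversions round-trip", {
  for (s in 1:25) {
    v <- with_seed(s, rnorm(3) * runif(1, 0, 3))
    R <- rotvec_to_matrix(v)
    expect_equal(rotvec_to_matrix(matrix_to_rotvec(R)), R, tolerance = 1e-9)
  }
})

test_that("transform JSON round-trips and validates schema", {
  path <- withr::local_tempfile(fileext = ".json")
  t1 <- random_pose(seed = 9)
  write_transform_json(t1, path)
  t2 <- read_transform_json(path)
  expect_pose_close(t1, t2, 1e-9, 1e-9)

  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$units <- "m"
  jsonlite::write_json(bad, path, digits = NA, auto_unbox = TRUE)
  expect_error(read_transform_json(path), class = "endonav_units_error")

  m <- rt_to_matrix4(t1); m[4, 1] <- 0.1
  expect_error(rt_from_matrix4(m), class = "endonav_invalid_transform")
})

test_that("look_at points the camera z axis at the target", {
  cam <- look_at(c(100, 50, 200), c(0, 0, 0))
  p <- rt_apply(cam, c(0, 0, 0))
  expect_equal(p[1:2], cbind(0, 0)[1, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(p[3], sqrt(100^2 + 50^2 + 200^2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pose_noise matches its stated conventions", {
  # rotation parameter is the mean absolute perturbation angle
  angs <- vapply(1:1500, function(s) {
    p <- pose_noise(rt_identity(), 0.1, 0, seed = s)
    pose_error(rt_identity(), p)[["rotation_deg"]]
  }, 0)
  expect_equal(mean(angs), 0.1, tolerance = 0.01)
  # translation parameter is the RMS displacement norm
  disp <- vapply(1:1500, function(s) {
    p <- pose_noise(rt_identity(), 0, 0.35, seed = s)
    sum(p$translation^2)
  }, 0)
  expect_equal(sqrt(mean(disp)), 0.35, tolerance = 0.02)
})
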