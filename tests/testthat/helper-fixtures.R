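# Shared fixtures, all generated in code.

# Zero-distortion test camera.
test_intrinsics <- function(dist = c(0, 0, 0, 0, 0), f = 1000) {
  camera_intrinsics(f, f, 640, 360, 1280, 720, dist = dist)
}

# Simulated detections of a board from known poses (noise optional).
simulate_views <- function(board, intrinsics, poses, noise_px = 0,
                           seed = NULL) {
  with_seed(seed, lapply(seq_along(poses), function(i) {
    obj <- cbind(board$points$x_mm, board$points$y_mm, 0)
    pr <- project_points(intrinsics, poses[[i]], obj)
    stopifnot(all(pr$visible))
    px <- pr$pixels
    if (noise_px > 0) px <- px + matrix(rnorm(length(px), 0, noise_px), ncol = 2)
    board_detection(i, board$points$id, px, board = board)
  }))
}

# Well-spread board poses for calibration tests: tilted, varying distance.
calibration_poses <- function(n = 10, seed = 42) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    tilt <- rotvec_to_matrix(unit_vector(rnorm(3)) * runif(1, 5, 25) * pi / 180)
    rigid_transform(tilt, c(runif(1, -120, -40), runif(1, -70, -10),
                            runif(1, 420, 620)))
  }))
}

# A small face-like scene for registration tests (shared, cached).
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(noise = noise_config_zero())
      cache <<- list(cfg = cfg, scene = build_scene(cfg, seed = 7L))
    }
    cache
  }
})

# Noiseless surface cloud seen from the tracking camera (camera frame).
face_cloud <- function(max_points = 2500, seed = 3L) {
  s <- small_scene()
  dm <- render_depth(s$scene$phantom, s$scene$trackcam_from_world,
                     s$cfg$depth_intrinsics, noise_config_zero(), seed = 0L)
  cl <- backproject_depth(dm)
  pts <- cl$points
  if (nrow(pts) > max_points)
    pts <- pts[with_seed(seed, sample.int(nrow(pts), max_points)), ]
  list(cloud = point_cloud(pts), scene = s$scene, cfg = s$cfg)
}

# Replace pts[idx, ] with displaced points guaranteed to lie at least
# min_dist from the mesh surface (rejection sampling, deterministic).
make_off_surface_outliers <- function(pts, idx, mesh, min_dist = 5,
                                      max_dist = 30, seed = 1L) {
  adj <- endonav:::mesh_two_ring(mesh)
  out <- pts[idx, , drop = FALSE]
  with_seed(seed, {
    todo <- seq_len(nrow(out))
    for (round in 1:50) {
      d <- matrix(rnorm(3 * length(todo)), ncol = 3)
      d <- d / sqrt(rowSums(d^2))
      cand <- pts[idx[todo], , drop = FALSE] +
        d * runif(length(todo), min_dist, max_dist)
      dist <- endonav:::icp_correspond(cand, mesh, adj)$d
      ok <- dist >= min_dist
      out[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
      if (!length(todo)) break
    }
    stopifnot(length(todo) == 0L)
  })
  res <- pts
  res[idx, ] <- out
  res
}

expect_pose_close <- function(a, b, rot_deg, trans_mm) {
  pe <- pose_error(a, b)
  expect_lt(pe[["rotation_deg"]], rot_deg)
  expect_lt(pe[["translation_mm"]], trans_mm)
}
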