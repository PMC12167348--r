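#' Sensor noise configuration
#'
#' Every stochastic hardware effect the simulation models, with the
#' convention each parameter is quoted in:
#' * `corner_px_sigma` — per-component Gaussian pixel noise on detected
#'   board corners (px).
#' * `board_occlusion` — fraction of visible board points removed per
#'   detection (deterministic count, seeded choice).
#' * `depth_sigma_mm` — additive Gaussian noise on valid depths (mm).
#' * `depth_dropout` — per-pixel probability a valid depth is invalidated.
#' * `tracker_trans_sigma_mm` — RMS of the tracker body-position error norm.
#' * `tracker_rot_sigma_deg` — mean absolute tracker body-orientation error.
#' * `pointer_sigma_mm` — per-axis Gaussian pointer-tip localization noise.
#' * `handeye_rot_deg`, `handeye_trans_mm` — fixed-magnitude error injected
#'   into the IR system's externally calibrated hand-eye transform.
#' * `ct_jitter_sigma_mm` — per-axis vertex jitter of the CT surface model.
#' * `seed` — master seed fanned out per stage via [child_seed()].
#'
#' `noise_config_zero()` returns the all-zero configuration used by the
#' noiseless-closure property.
#'
#' @param corner_px_sigma,board_occlusion,depth_sigma_mm,depth_dropout
#'   See above.
#' @param tracker_trans_sigma_mm,tracker_rot_sigma_deg,pointer_sigma_mm
#'   See above.
#' @param handeye_rot_deg,handeye_trans_mm,ct_jitter_sigma_mm,seed See above.
#' @return A `noise_config` object.
#' @export
noise_config <- function(corner_px_sigma = 0.5, board_occlusion = 0,
                         depth_sigma_mm = 0.5, depth_dropout = 0.05,
                         tracker_trans_sigma_mm = 0.35,
                         tracker_rot_sigma_deg = 0.1,
                         pointer_sigma_mm = 0.3,
                         handeye_rot_deg = 0.15, handeye_trans_mm = 0.5,
                         ct_jitter_sigma_mm = 0.1, seed = 0L) {
  vals <- c(corner_px_sigma, depth_sigma_mm, tracker_trans_sigma_mm,
            tracker_rot_sigma_deg, pointer_sigma_mm, handeye_rot_deg,
            handeye_trans_mm, ct_jitter_sigma_mm)
  if (any(vals < 0)) stop_endonav("noise magnitudes must be >= 0",
                                  "endonav_invalid_config")
  if (board_occlusion < 0 || board_occlusion > 1 ||
      depth_dropout < 0 || depth_dropout > 1)
    stop_endonav("fractions must be in [0, 1]", "endonav_invalid_config")
  structure(list(corner_px_sigma = corner_px_sigma,
                 board_occlusion = board_occlusion,
                 depth_sigma_mm = depth_sigma_mm,
                 depth_dropout = depth_dropout,
                 tracker_trans_sigma_mm = tracker_trans_sigma_mm,
                 tracker_rot_sigma_deg = tracker_rot_sigma_deg,
                 pointer_sigma_mm = pointer_sigma_mm,
                 handeye_rot_deg = handeye_rot_deg,
                 handeye_trans_mm = handeye_trans_mm,
                 ct_jitter_sigma_mm = ct_jitter_sigma_mm,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' @rdname noise_config
#' @export
noise_config_zero <- function(seed = 0L) {
  noise_config(corner_px_sigma = 0, board_occlusion = 0, depth_sigma_mm = 0,
               depth_dropout = 0, tracker_trans_sigma_mm = 0,
               tracker_rot_sigma_deg = 0, pointer_sigma_mm = 0,
               handeye_rot_deg = 0, handeye_trans_mm = 0,
               ct_jitter_sigma_mm = 0, seed = seed)
}

#' Read and write noise configurations as YAML
#' @param noise A `noise_config`.
#' @param path File path.
#' @export
write_noise_yaml <- function(noise, path) {
  yaml::write_yaml(unclass(noise), path)
  invisible(path)
}

#' @rdname write_noise_yaml
#' @return `read_noise_yaml`: a `noise_config`.
#' @export
read_noise_yaml <- function(path) {
  do.call(noise_config, yaml::read_yaml(path))
}

#' Render a depth map of the phantom face
#'
#' Ray-casts every pixel of the depth camera against the face mesh
#' (Moller-Trumbore, in the camera frame so the returned value is z-depth),
#' then applies seeded Gaussian depth noise and dropout. Deterministic per
#' seed.
#'
#' @param phantom A `phantom_model` (its `world_from_ct` places the face).
#' @param camera_from_world Depth camera pose.
#' @param intrinsics Depth camera `camera_intrinsics`.
#' @param noise A `noise_config` (uses `depth_sigma_mm`, `depth_dropout`).
#' @param seed Seed for the noise.
#' @return A `depth_map`; attribute `"empty"` flags an all-miss render.
#' @export
render_depth <- function(phantom, camera_from_world, intrinsics,
                         noise = noise_config_zero(), seed = 0L) {
  check_intrinsics(intrinsics)
  mesh <- if (inherits(phantom, "phantom_model")) phantom$face else phantom
  cam_from_ct <- if (inherits(phantom, "phantom_model"))
    rt_compose(camera_from_world, phantom$world_from_ct) else camera_from_world
  V <- rt_apply(cam_from_ct, mesh$vertices)
  w <- intrinsics$width; h <- intrinsics$height
  grid <- expand.grid(u = seq_len(w) - 1, v = seq_len(h) - 1)
  nrm <- pixel_to_normalized(intrinsics, cbind(grid$u, grid$v))
  dirs <- cbind(nrm[, 1], nrm[, 2], 1)
  t <- .raycast_cpp(dirs, V, mesh$faces)
  depth <- matrix(0, h, w)
  hit <- is.finite(t)
  depth[cbind(grid$v + 1L, grid$u + 1L)[hit, , drop = FALSE]] <- t[hit]
  dm <- with_seed(seed, {
    if (noise$depth_sigma_mm > 0) {
      nz <- depth != 0
      depth[nz] <- pmax(1e-6, depth[nz] + rnorm(sum(nz), 0, noise$depth_sigma_mm))
    }
    if (noise$depth_dropout > 0) {
      nz <- which(depth != 0)
      drop <- nz[runif(length(nz)) < noise$depth_dropout]
      depth[drop] <- 0
    }
    depth_map(depth, intrinsics)
  })
  if (!any(hit)) attr(dm, "empty") <- TRUE
  dm
}

#' Simulate a board detection
#'
#' Projects the board's points into the camera, keeps the visible ones,
#' removes a seeded occluded fraction (deterministic count), and adds
#' per-component Gaussian pixel noise. Deterministic per seed.
#'
#' @param board A `marker_board`.
#' @param world_from_board Board pose in the world frame.
#' @param camera_from_world Camera pose.
#' @param intrinsics Camera `camera_intrinsics`.
#' @param noise A `noise_config` (uses `corner_px_sigma`, `board_occlusion`).
#' @param seed Seed.
#' @param frame Frame index recorded on the detection.
#' @param camera_id Camera identifier recorded on the detection.
#' @return A `board_detection`; attribute `"empty"` flags zero points in
#'   view.
#' @export
observe_board <- function(board, world_from_board, camera_from_world,
                          intrinsics, noise = noise_config_zero(), seed = 0L,
                          frame = 0L, camera_id = "camera") {
  pts3 <- cbind(board$points$x_mm, board$points$y_mm, 0)
  world <- rt_apply(world_from_board, pts3)
  pr <- project_points(intrinsics, camera_from_world, world)
  vis <- which(pr$visible)
  det <- with_seed(seed, {
    keep <- vis
    if (noise$board_occlusion > 0 && length(vis)) {
      n_drop <- round(noise$board_occlusion * length(vis))
      if (n_drop > 0) keep <- sort(sample(vis, length(vis) - n_drop))
    }
    px <- pr$pixels[keep, , drop = FALSE]
    if (noise$corner_px_sigma > 0 && length(keep))
      px <- px + matrix(rnorm(2 * length(keep), 0, noise$corner_px_sigma),
                        ncol = 2)
    board_detection(frame, board$points$id[keep], px, camera_id = camera_id,
                    board = board)
  })
  if (length(vis) == 0L) attr(det, "empty") <- TRUE
  det
}

#' Tracked-body rig of the IR comparator
#'
#' Bundles the IR tracker pose and the two rigid bodies it observes: the
#' patient reference clamped to the holder and the endoscope reference on
#' the scope.
#'
#' @param tracker_from_world IR tracker pose.
#' @param ct_from_patientref Mounting of the patient-reference body in the
#'   CT frame.
#' @param endocam_from_endoref Hand-eye transform from the endoscope
#'   reference body to the endoscope camera.
#' @return A `tracker_rig`.
#' @export
tracker_rig <- function(tracker_from_world, ct_from_patientref,
                        endocam_from_endoref) {
  structure(list(tracker_from_world = check_transform(tracker_from_world),
                 ct_from_patientref = check_transform(ct_from_patientref),
                 endocam_from_endoref = check_transform(endocam_from_endoref)),
            class = "tracker_rig")
}

#' Simulate one IR tracker frame
#'
#' Computes the true poses of the patient-reference and endoscope-reference
#' bodies in the tracker frame and perturbs each with seeded body-frame pose
#' noise ([pose_noise()]). Deterministic per (frame, seed).
#'
#' @param rig A [tracker_rig()].
#' @param phantom A `phantom_model` (for the holder pose).
#' @param endocam_from_world Endoscope camera pose this frame.
#' @param noise A `noise_config`.
#' @param frame Frame index.
#' @param seed Seed.
#' @return A `tracker_frame` with `tracker_from_patientref`,
#'   `tracker_from_endoref`, and per-body `valid` flags.
#' @export
observe_tracker <- function(rig, phantom, endocam_from_world,
                            noise = noise_config_zero(), frame = 0L,
                            seed = 0L) {
  t_pat <- rt_compose(rig$tracker_from_world,
                      rt_compose(phantom$world_from_ct, rig$ct_from_patientref))
  t_endo <- rt_compose(rig$tracker_from_world,
                       rt_compose(rt_invert(endocam_from_world),
                                  rig$endocam_from_endoref))
  s <- child_seed(seed, "tracker", frame)
  with_seed(s, {
    t_pat <- pose_noise(t_pat, noise$tracker_rot_sigma_deg,
                        noise$tracker_trans_sigma_mm)
    t_endo <- pose_noise(t_endo, noise$tracker_rot_sigma_deg,
                         noise$tracker_trans_sigma_mm)
    structure(list(frame = frame, tracker_from_patientref = t_pat,
                   tracker_from_endoref = t_endo,
                   valid = c(patientref = TRUE, endoref = TRUE)),
              class = "tracker_frame")
  })
}

#' Sample the base fiducials with the tracked pointer
#'
#' Expresses the phantom's fiducials in the patient-reference frame and adds
#' seeded isotropic Gaussian noise of per-axis scale `noise_mm`, emulating
#' pointer-tip localization error during fiducial digitization.
#'
#' @param phantom A `phantom_model`.
#' @param patientref_from_ct True pose of the CT frame in the
#'   patient-reference body frame.
#' @param noise_mm Per-axis Gaussian sd (mm), >= 0.
#' @param seed Seed.
#' @return Data frame `id`, `x_mm`, `y_mm`, `z_mm` (patient-reference
#'   frame).
#' @export
sample_fiducials_with_pointer <- function(phantom, patientref_from_ct,
                                          noise_mm = 0.3, seed = 0L) {
  if (noise_mm < 0) stop_endonav("noise_mm must be >= 0", "endonav_invalid_config")
  fid <- phantom$fiducials
  p <- rt_apply(patientref_from_ct, cbind(fid$x_mm, fid$y_mm, fid$z_mm))
  p <- with_seed(seed, p + matrix(rnorm(length(p), 0, noise_mm), ncol = 3))
  data.frame(id = fid$id, x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3])
}

#' Read and write tracker frames as CSV
#'
#' One row per (frame, body): `frame, body, valid`, then the body pose as a
#' row-major 4x4 transform (`m00` ... `m33`).
#'
#' @param frames List of `tracker_frame` objects.
#' @param path File path.
#' @export
write_tracker_csv <- function(frames, path) {
  if (inherits(frames, "tracker_frame")) frames <- list(frames)
  rows <- do.call(rbind, lapply(frames, function(fr) {
    do.call(rbind, lapply(c("patientref", "endoref"), function(body) {
      t <- if (body == "patientref") fr$tracker_from_patientref else
        fr$tracker_from_endoref
      m <- as.numeric(t(rt_to_matrix4(t)))
      cbind(data.frame(frame = fr$frame, body = body,
                       valid = unname(fr$valid[body])),
            as.data.frame(as.list(stats::setNames(
              m, sprintf("m%d%d", rep(0:3, each = 4), rep(0:3, 4))))))
    }))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracker_csv
#' @return `read_tracker_csv`: list of `tracker_frame` objects.
#' @export
read_tracker_csv <- function(path) {
  d <- read.csv(path)
  lapply(unique(d$frame), function(f) {
    sub <- d[d$frame == f, ]
    get_t <- function(body) {
      r <- sub[sub$body == body, ]
      rt_from_matrix4(matrix(as.numeric(r[1, grep("^m", names(sub))]),
                             4, 4, byrow = TRUE))
    }
    structure(list(frame = f,
                   tracker_from_patientref = get_t("patientref"),
                   tracker_from_endoref = get_t("endoref"),
                   valid = c(patientref = as.logical(sub$valid[sub$body == "patientref"]),
                             endoref = as.logical(sub$valid[sub$body == "endoref"]))),
              class = "tracker_frame")
  })
}
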