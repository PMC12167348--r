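#' Default configuration of the two-system comparison experiment
#'
#' Encodes the desk-scale stand-in for the published bench setup: a
#' stationary phantom, an endoscope with an on-board tracking camera about
#' 0.3 m from the reference board, and an IR tracker about 2 m away.
#' Cameras, boards, geometry, noise, and repetition structure are all here;
#' every entry can be overridden.
#'
#' @param noise A [noise_config()].
#' @param n_calib_frames Paired-pose calibration frames (default 20).
#' @param systems Which systems to simulate (`"ours"`, `"ir"`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(noise = noise_config(),
                              n_calib_frames = 20L,
                              systems = c("ours", "ir")) {
  list(
    phantom = phantom_params(),
    noise = noise,
    n_calib_frames = as.integer(n_calib_frames),
    systems = systems,
    # endoscope: 1920x1080 wide-angle with mild barrel distortion
    endo_intrinsics = camera_intrinsics(1100, 1100, 960, 540, 1920, 1080,
                                        dist = c(-0.15, 0.03, 0, 0, 0)),
    # on-board tracking camera: RealSense-like colour stream (the stream
    # that tracks the board), factory rectified
    track_intrinsics = camera_intrinsics(1380, 1380, 960, 540, 1920, 1080),
    # depth stream rendered at half the tracking-camera resolution
    depth_intrinsics = camera_intrinsics(155, 155, 106, 60, 212, 120),
    tracking_board = make_board(6, 4, 15, id = "reference"),
    calib_board = make_board(5, 9, 20, id = "charuco"),
    # viewpoints (CT frame): endoscope ~0.22 m from the target grid,
    # on-board camera ~0.32 m from the reference board, tracker ~2 m out
    endo_eye_ct = c(0, -170, 210),
    endo_target_ct = c(0, -10, 40),
    track_eye_ct = c(55, -230, 250),
    track_target_ct = c(70, -10, 20),
    tracker_eye_ct = c(300, -1800, 800),
    ct_from_patientref = rigid_transform(
      rotation_about("z", 30) %*% rotation_about("x", 20), c(-110, -20, 25)),
    endocam_from_endoref = rigid_transform(rotation_about("y", 15),
                                           c(15, 35, -120)),
    prior_rot_deg = 5, prior_trans_mm = 10,
    icp = icp_config(max_iterations = 100L),
    icp_max_points = 3500L
  )
}

#' Ground-truth scene for one experiment repetition
#'
#' Derives every true pose of the simulated theatre from the configuration:
#' holder, cameras, rigid endoscope/tracking-camera rig, board, IR rig.
#'
#' @param config An [experiment_config()].
#' @param seed Seed (reserved for randomized scene variants).
#' @return A `scene_truth` list of `rigid_transform`s plus the phantom.
#' @export
build_scene <- function(config, seed = 0L) {
  phantom <- make_phantom(config$phantom, seed = seed)
  w_ct <- phantom$world_from_ct
  ct2w <- function(p) as.numeric(rt_apply(w_ct, p))
  endocam_from_world <- look_at(ct2w(config$endo_eye_ct),
                                ct2w(config$endo_target_ct),
                                up = c(0, 0, 1))
  trackcam_from_world <- look_at(ct2w(config$track_eye_ct),
                                 ct2w(config$track_target_ct),
                                 up = c(0, 0, 1))
  endo_from_trackcam <- rt_compose(endocam_from_world,
                                   rt_invert(trackcam_from_world))
  tracker_from_world <- look_at(ct2w(config$tracker_eye_ct), ct2w(c(0, 0, 0)),
                                up = c(0, 0, 1))
  rig <- tracker_rig(tracker_from_world, config$ct_from_patientref,
                     config$endocam_from_endoref)
  world_from_board <- rt_compose(w_ct, phantom$ct_from_board)
  list(phantom = phantom,
       endocam_from_world = endocam_from_world,
       trackcam_from_world = trackcam_from_world,
       endo_from_trackcam = endo_from_trackcam,
       world_from_board = world_from_board,
       rig = rig,
       endocam_from_ct = rt_compose(endocam_from_world, w_ct),
       trackcam_from_ct = rt_compose(trackcam_from_world, w_ct))
}

# Calibration-board poses for paired-pose frames: varied positions and tilts
# in front of the endoscope, far enough that both cameras see the board.
calib_board_pose <- function(config, scene, frame, seed) {
  extent <- c((config$calib_board$cols - 2) * config$calib_board$square_mm,
              (config$calib_board$rows - 2) * config$calib_board$square_mm)
  with_seed(child_seed(seed, "calibpose", frame), {
    for (try in 1:25) {
      tilt <- rotvec_to_matrix(random_unit_vector() * runif(1, 0, 25) * pi / 180)
      offs <- c(runif(1, -30, 30), runif(1, -20, 20), runif(1, 260, 340))
      cam_from_board <- rigid_transform(tilt, offs - c(extent / 2, 0))
      world_from_board <- rt_compose(rt_invert(scene$endocam_from_world),
                                     cam_from_board)
      pts <- rt_apply(world_from_board,
                      cbind(config$calib_board$points$x_mm,
                            config$calib_board$points$y_mm, 0))
      ok <- all(project_points(config$endo_intrinsics,
                               scene$endocam_from_world, pts)$visible) &&
        all(project_points(config$track_intrinsics,
                           scene$trackcam_from_world, pts)$visible)
      if (ok) return(world_from_board)
    }
    world_from_board  # last try; partial views are tolerated downstream
  })
}

#' Simulate the on-board system's extrinsic calibration
#'
#' Generates `n_calib_frames` frames in which the calibration board is seen
#' by both the endoscope and the tracking camera, estimates the two board
#' poses per frame from (noisy) corner detections, and fuses them with
#' [extrinsic_from_paired_poses()].
#'
#' @param config,scene,seed Experiment configuration, scene truth, seed.
#' @return The [extrinsic_from_paired_poses()] result.
#' @export
simulate_extrinsic_calibration <- function(config, scene, seed = 0L) {
  frames <- integer(0); e_list <- list(); t_list <- list()
  for (f in seq_len(config$n_calib_frames)) {
    wfb <- calib_board_pose(config, scene, f, seed)
    det_e <- observe_board(config$calib_board, wfb, scene$endocam_from_world,
                           config$endo_intrinsics, config$noise,
                           seed = child_seed(seed, "calib_endo", f),
                           frame = f, camera_id = "endoscope")
    det_t <- observe_board(config$calib_board, wfb, scene$trackcam_from_world,
                           config$track_intrinsics, config$noise,
                           seed = child_seed(seed, "calib_track", f),
                           frame = f, camera_id = "trackingcam")
    pe <- tryCatch(board_pose_from_detection(config$endo_intrinsics,
                                             config$calib_board, det_e),
                   endonav_error = function(e) NULL)
    pt <- tryCatch(board_pose_from_detection(config$track_intrinsics,
                                             config$calib_board, det_t),
                   endonav_error = function(e) NULL)
    if (is.null(pe) || is.null(pt)) next
    frames <- c(frames, f)
    e_list[[length(e_list) + 1L]] <- pe$transform
    t_list[[length(t_list) + 1L]] <- pt$transform
  }
  extrinsic_from_paired_poses(paired_pose_set(frames, e_list, t_list))
}

#' Simulate the on-board system's automatic surface registration
#'
#' Renders a (noisy) depth map from the tracking camera, back-projects it,
#' and registers the cloud to the CT surface model starting from a prior
#' offset from the truth by the configured magnitude; simultaneously tracks
#' the board to fold the registration into the board reference.
#'
#' @param config,scene,seed Experiment configuration, scene truth, seed.
#' @param ct_mesh CT surface model (defaults to the jittered copy the noise
#'   config prescribes).
#' @return List with `board_from_ct`, `trackcam_from_ct`, `icp_result`,
#'   `board_rms`.
#' @export
simulate_registration <- function(config, scene, seed = 0L, ct_mesh = NULL) {
  if (is.null(ct_mesh))
    ct_mesh <- ct_surface_model(scene$phantom,
                                jitter_sigma_mm = config$noise$ct_jitter_sigma_mm,
                                seed = child_seed(seed, "ct"))
  dm <- render_depth(scene$phantom, scene$trackcam_from_world,
                     config$depth_intrinsics, config$noise,
                     seed = child_seed(seed, "depth"))
  cloud <- backproject_depth(dm)
  prior <- perturb_pose(scene$trackcam_from_ct, config$prior_rot_deg,
                        config$prior_trans_mm,
                        seed = child_seed(seed, "prior"))
  reg <- register_depth_to_ct(cloud, ct_mesh, prior, config$icp,
                              max_points = config$icp_max_points,
                              seed = child_seed(seed, "subsample"))
  det <- observe_board(config$tracking_board, scene$world_from_board,
                       scene$trackcam_from_world, config$track_intrinsics,
                       config$noise, seed = child_seed(seed, "board_reg"),
                       frame = 0L, camera_id = "trackingcam")
  bp <- board_pose_from_detection(config$track_intrinsics,
                                  config$tracking_board, det)
  list(board_from_ct = compose_ct_to_reference(reg$camera_from_ct,
                                               bp$transform),
       trackcam_from_ct = reg$camera_from_ct,
       icp_result = reg$result, board_rms = bp$rms)
}

#' Run both navigation systems once and report their projected TRE
#'
#' One complete repetition of the evaluation protocol: calibration,
#' registration and tracking are simulated end to end for the on-board
#' system and the IR-tracked comparator on the same phantom instance, and
#' each system's overlay is scored against the ground-truth chain with
#' [projected_tre()].
#'
#' @param config An [experiment_config()].
#' @param seed Repetition seed.
#' @return List with `ours` and `ir` (`tre_report` or `NULL` if not
#'   simulated), the underlying chains, and stage diagnostics.
#' @export
run_single_repetition <- function(config, seed = 0L) {
  scene <- build_scene(config, seed = seed)
  targets <- scene$phantom$targets
  truth_chain <- scene$endocam_from_ct
  out <- list(seed = seed)
  if ("ours" %in% config$systems) {
    calib <- simulate_extrinsic_calibration(config, scene,
                                            seed = child_seed(seed, "calib"))
    reg <- simulate_registration(config, scene,
                                 seed = child_seed(seed, "registration"))
    det_eval <- observe_board(config$tracking_board, scene$world_from_board,
                              scene$trackcam_from_world,
                              config$track_intrinsics, config$noise,
                              seed = child_seed(seed, "board_eval"),
                              frame = 1L, camera_id = "trackingcam")
    bp_eval <- board_pose_from_detection(config$track_intrinsics,
                                         config$tracking_board, det_eval)
    overlay <- our_overlay_chain(bp_eval$transform,
                                 calib$endoscope_from_trackingcam,
                                 reg$board_from_ct, config$endo_intrinsics,
                                 targets)
    out$ours <- projected_tre(targets, truth_chain, overlay$endocam_from_ct,
                              config$endo_intrinsics, system = "ours")
    out$ours_chain <- overlay$endocam_from_ct
    out$ours_diag <- list(calib = calib, registration = reg)
  }
  if ("ir" %in% config$systems) {
    handeye <- perturb_pose(scene$rig$endocam_from_endoref,
                            config$noise$handeye_rot_deg,
                            config$noise$handeye_trans_mm,
                            seed = child_seed(seed, "handeye"))
    patientref_from_ct_true <- rt_invert(scene$rig$ct_from_patientref)
    sampled <- sample_fiducials_with_pointer(scene$phantom,
                                             patientref_from_ct_true,
                                             config$noise$pointer_sigma_mm,
                                             seed = child_seed(seed, "pointer"))
    reg_ir <- register_ir(phantom_fiducial_set(scene$phantom), sampled)
    frame <- observe_tracker(scene$rig, scene$phantom,
                             scene$endocam_from_world, config$noise,
                             frame = 1L, seed = child_seed(seed, "track_eval"))
    overlay_ir <- ir_overlay_chain(frame, handeye, reg_ir$patientref_from_ct,
                                   config$endo_intrinsics, targets)
    if (identical(overlay_ir$status, "ok")) {
      out$ir <- projected_tre(targets, truth_chain,
                              overlay_ir$endocam_from_ct,
                              config$endo_intrinsics, system = "ir")
      out$ir_chain <- overlay_ir$endocam_from_ct
    }
    out$ir_diag <- list(fre = reg_ir$fre)
  }
  out
}

#' Seeded Monte-Carlo comparison of the two systems
#'
#' Repeats [run_single_repetition()] with per-repetition child seeds and
#' aggregates each system's mean projected TRE. A failed stage is recorded
#' for its repetition, never fatal to the batch.
#'
#' @param config An [experiment_config()].
#' @param n_repetitions Number of repetitions.
#' @param seed Master seed.
#' @return A `comparison_result`: `per_rep` data frame (one row per
#'   repetition per system), `summary` data frame (mean, sd, n per system),
#'   `failures`.
#' @export
run_comparison_experiment <- function(config = experiment_config(),
                                      n_repetitions = 100L, seed = 1L) {
  rows <- list(); failures <- list()
  for (r in seq_len(n_repetitions)) {
    rep_seed <- child_seed(seed, "rep", r)
    res <- tryCatch(run_single_repetition(config, seed = rep_seed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, error = conditionMessage(res))
      next
    }
    for (sys in intersect(c("ours", "ir"), names(res))) {
      rep_report <- res[[sys]]
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, system = sys, mean_tre_mm = rep_report$mean_mm,
                   sd_tre_mm = rep_report$sd_mm, n_targets = rep_report$n,
                   mean_tre_px = mean(rep_report$pixel_error_px))
    }
  }
  per_rep <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_rep, per_rep$system), function(d)
    data.frame(system = d$system[1], mean_tre_mm = mean(d$mean_tre_mm),
               sd_tre_mm = sd(d$mean_tre_mm), n_reps = nrow(d))))
  rownames(summary) <- NULL
  structure(list(per_rep = per_rep, summary = summary,
                 failures = if (length(failures)) do.call(rbind, failures)
                 else NULL),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-5s mean projected TRE %.3f (+/- %.3f) mm over %d repetitions\n",
                x$summary$system[i], x$summary$mean_tre_mm[i],
                x$summary$sd_tre_mm[i], x$summary$n_reps[i]))
  if (!is.null(x$failures))
    cat(sprintf("  %d failed repetition(s)\n", nrow(x$failures)))
  invisible(x)
}

#' Write comparison results to disk
#'
#' CSV with one row per repetition per system plus a JSON summary.
#'
#' @param result A `comparison_result`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @export
write_comparison_result <- function(result, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) write.csv(result$per_rep, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- split(result$summary, result$summary$system)
    jsonlite::write_json(
      lapply(s, function(d) list(mean_tre_mm = d$mean_tre_mm,
                                 sd_tre_mm = d$sd_tre_mm, n_reps = d$n_reps)),
      json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(result)
}
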