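#' Paired pose sets for extrinsic calibration
#'
#' Frames in which the calibration board was visible from both the endoscope
#' and the on-board tracking camera, each contributing the two estimated
#' board poses.
#'
#' @param frames Integer frame indices (unique).
#' @param endoscope_from_board List of `rigid_transform`s.
#' @param trackingcam_from_board List of `rigid_transform`s.
#' @return A `paired_pose_set`.
#' @export
paired_pose_set <- function(frames, endoscope_from_board,
                            trackingcam_from_board) {
  frames <- as.integer(frames)
  if (anyDuplicated(frames))
    stop_endonav("frame indices must be unique", "endonav_invalid_pairs")
  n <- length(frames)
  if (n < 1L || length(endoscope_from_board) != n ||
      length(trackingcam_from_board) != n)
    stop_endonav("need >= 1 pair and equal-length pose lists",
                 "endonav_invalid_pairs")
  lapply(endoscope_from_board, check_transform)
  lapply(trackingcam_from_board, check_transform)
  structure(list(frames = frames,
                 endoscope_from_board = endoscope_from_board,
                 trackingcam_from_board = trackingcam_from_board),
            class = "paired_pose_set")
}

# Chordal mean rotation: orthogonal projection of the arithmetic mean.
chordal_mean_rotation <- function(rotations) {
  m <- Reduce(`+`, rotations) / length(rotations)
  project_to_rotation(m)
}

#' Extrinsic calibration from paired board poses
#'
#' Each frame in which both cameras see the board yields a closed-form
#' estimate `E_i = endoscope_from_board_i o inv(trackingcam_from_board_i)`
#' of the fixed endoscope-to-tracking-camera transform. Frames are fused by
#' chordal rotation averaging (orthogonal projection of the mean rotation
#' matrix) and arithmetic mean translation; residuals are the pose errors
#' of the per-frame estimates against the average.
#'
#' @param pairs A [paired_pose_set()].
#' @param reject_outliers Optionally drop frames whose residual exceeds 3x
#'   the median residual and re-average once (off by default).
#' @return List with `endoscope_from_trackingcam` (`rigid_transform`),
#'   `residuals` (data frame: frame, rotation_deg, translation_mm), and
#'   `n_used`.
#' @export
extrinsic_from_paired_poses <- function(pairs, reject_outliers = FALSE) {
  if (!inherits(pairs, "paired_pose_set"))
    stop_endonav("expected a paired_pose_set", "endonav_invalid_pairs")
  per_frame <- lapply(seq_along(pairs$frames), function(i)
    rt_compose(pairs$endoscope_from_board[[i]],
               rt_invert(pairs$trackingcam_from_board[[i]])))
  average <- function(est) {
    rigid_transform(chordal_mean_rotation(lapply(est, `[[`, "rotation")),
                    rowMeans(vapply(est, `[[`, numeric(3), "translation")))
  }
  avg <- average(per_frame)
  resid <- t(vapply(per_frame, pose_error, numeric(2), b = avg))
  used <- seq_along(per_frame)
  if (reject_outliers && length(per_frame) >= 3L) {
    score <- resid[, 1] / max(median(resid[, 1]), 1e-12) +
      resid[, 2] / max(median(resid[, 2]), 1e-12)
    keep <- which(resid[, 1] <= 3 * median(resid[, 1]) + 1e-12 &
                    resid[, 2] <= 3 * median(resid[, 2]) + 1e-12)
    if (length(keep) >= 1L && length(keep) < length(per_frame)) {
      avg <- average(per_frame[keep])
      resid <- t(vapply(per_frame, pose_error, numeric(2), b = avg))
      used <- keep
    }
  }
  list(endoscope_from_trackingcam = avg,
       residuals = data.frame(frame = pairs$frames,
                              rotation_deg = resid[, 1],
                              translation_mm = resid[, 2]),
       n_used = length(used))
}

#' Read and write paired pose sets as JSON
#'
#' Schema: a list of `{frame, T_endo_board, T_track_board}` entries, each
#' transform in the 4x4 `{"units":"mm","matrix":...}` form.
#'
#' @param pairs A `paired_pose_set`.
#' @param path File path.
#' @export
write_paired_poses_json <- function(pairs, path) {
  entries <- lapply(seq_along(pairs$frames), function(i) {
    list(frame = pairs$frames[i],
         T_endo_board = list(units = "mm",
                             matrix = rt_to_matrix4(pairs$endoscope_from_board[[i]])),
         T_track_board = list(units = "mm",
                              matrix = rt_to_matrix4(pairs$trackingcam_from_board[[i]])))
  })
  jsonlite::write_json(entries, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_paired_poses_json
#' @return `read_paired_poses_json`: a `paired_pose_set`.
#' @export
read_paired_poses_json <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_t <- function(o) {
    if (!identical(o$units, "mm"))
      stop_endonav("paired poses must declare units \"mm\"", "endonav_units_error")
    rt_from_matrix4(do.call(rbind, lapply(o$matrix, unlist)))
  }
  paired_pose_set(vapply(entries, function(e) e$frame, 1),
                  lapply(entries, function(e) parse_t(e$T_endo_board)),
                  lapply(entries, function(e) parse_t(e$T_track_board)))
}
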