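#' Marker-based overlay chain of the proposed system
#'
#' Projects CT-frame targets through the single-reference chain of the
#' on-board system: `endo_from_trackcam o trackcam_from_board_t o
#' board_from_ct`. `trackcam_from_board_t` is the board pose tracked at the
#' current frame; when the board was not detected the caller holds the
#' previous pose (documented policy) — pass `NULL` to receive a `no_pose`
#' status instead of pixels.
#'
#' @param trackcam_from_board_t Board pose this frame (or `NULL`).
#' @param endo_from_trackcam Extrinsic calibration estimate.
#' @param board_from_ct Persistent registration.
#' @param intrinsics Endoscope `camera_intrinsics`.
#' @param targets_ct N x 3 CT-frame targets (mm).
#' @return List with `status` (`"ok"` or `"no_pose"`), and when ok:
#'   `pixels`, `visible`, `endocam_from_ct`.
#' @export
our_overlay_chain <- function(trackcam_from_board_t, endo_from_trackcam,
                              board_from_ct, intrinsics, targets_ct) {
  if (is.null(trackcam_from_board_t)) return(list(status = "no_pose"))
  chain <- rt_compose(endo_from_trackcam,
                      rt_compose(trackcam_from_board_t, board_from_ct))
  pr <- project_points(intrinsics, chain, targets_ct)
  list(status = "ok", pixels = pr$pixels, visible = pr$visible,
       endocam_from_ct = chain)
}

#' Projected target registration error report
#'
#' For each target, the true pixel (through the ground-truth chain) and the
#' overlay pixel (through the estimated chain) are both back-projected onto
#' the plane perpendicular to the optical axis at the target's true
#' camera-frame depth; the error is the Euclidean distance in that plane, in
#' mm. This is the depth-aware metric-plane conversion of the image-space
#' overlay offset and reduces to the intuition `z * delta_px / f`. Raw pixel
#' distances are also reported.
#'
#' @param targets_ct N x 3 true target locations (mm, CT frame).
#' @param truth_chain Ground-truth `endocam_from_ct`.
#' @param estimated_chain Estimated `endocam_from_ct`.
#' @param intrinsics Endoscope `camera_intrinsics`.
#' @param system Label for the report.
#' @return A `tre_report`: `per_target_mm`, `pixel_error_px`, `mean_mm`,
#'   `sd_mm`, `n`, `system`.
#' @export
projected_tre <- function(targets_ct, truth_chain, estimated_chain,
                          intrinsics, system = "system") {
  targets_ct <- as_points_matrix(targets_ct, "targets")
  pr_true <- project_points(intrinsics, truth_chain, targets_ct)
  pr_est <- project_points(intrinsics, estimated_chain, targets_ct)
  vis <- pr_true$visible & pr_est$visible
  if (!any(vis))
    stop_endonav("no target is visible through both chains",
                 "endonav_no_visible_targets")
  z <- pr_true$depth[vis]
  n_true <- pixel_to_normalized(intrinsics, pr_true$pixels[vis, , drop = FALSE])
  n_est <- pixel_to_normalized(intrinsics, pr_est$pixels[vis, , drop = FALSE])
  err <- z * sqrt(rowSums((n_true - n_est)^2))
  px <- sqrt(rowSums((pr_true$pixels[vis, , drop = FALSE] -
                        pr_est$pixels[vis, , drop = FALSE])^2))
  tre_report(err, px, system)
}

#' @rdname projected_tre
#' @param per_target_mm Per-target metric errors (mm).
#' @param pixel_error_px Per-target pixel distances (px).
#' @export
tre_report <- function(per_target_mm, pixel_error_px = NULL,
                       system = "system") {
  if (any(per_target_mm < 0)) stop_endonav("errors must be >= 0",
                                           "endonav_invalid_report")
  structure(list(per_target_mm = as.numeric(per_target_mm),
                 pixel_error_px = pixel_error_px,
                 mean_mm = mean(per_target_mm),
                 sd_mm = if (length(per_target_mm) > 1) sd(per_target_mm) else 0,
                 n = length(per_target_mm), system = system),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report '%s'> projected TRE %.3f (+/- %.3f) mm over %d targets\n",
              x$system, x$mean_mm, x$sd_mm, x$n))
  invisible(x)
}
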