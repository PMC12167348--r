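#' Fiducial sets in the CT frame
#'
#' @param ids Unique fiducial ids (>= 3).
#' @param points_ct N x 3 CT-frame coordinates (mm).
#' @return A `fiducial_set`.
#' @export
fiducial_set <- function(ids, points_ct) {
  points_ct <- as_points_matrix(points_ct, "fiducials")
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop_endonav("fiducial ids must be unique",
                                       "endonav_invalid_fiducials")
  if (length(ids) < 3L || nrow(points_ct) != length(ids))
    stop_endonav("need >= 3 fiducials with one coordinate row each",
                 "endonav_invalid_fiducials")
  structure(list(ids = ids, points_ct = points_ct), class = "fiducial_set")
}

#' @rdname fiducial_set
#' @param phantom A `phantom_model`.
#' @export
phantom_fiducial_set <- function(phantom) {
  fiducial_set(phantom$fiducials$id,
               cbind(phantom$fiducials$x_mm, phantom$fiducials$y_mm,
                     phantom$fiducials$z_mm))
}

#' Point-based registration of the IR comparator
#'
#' Pairs pointer samples with the CT fiducials by id and delegates to the
#' closed-form [procrustes_register()]. Proceeds with a warning when some
#' fiducials are missing, as long as at least 3 pairs remain.
#'
#' @param fiducials_ct A [fiducial_set()].
#' @param sampled Data frame `id`, `x_mm`, `y_mm`, `z_mm` of pointer samples
#'   in the patient-reference frame.
#' @return List with `patientref_from_ct` (`rigid_transform`), `fre` (mm),
#'   and `n_used`.
#' @export
register_ir <- function(fiducials_ct, sampled) {
  if (!inherits(fiducials_ct, "fiducial_set"))
    stop_endonav("expected a fiducial_set", "endonav_invalid_fiducials")
  m <- match(sampled$id, fiducials_ct$ids)
  if (all(is.na(m)))
    stop_endonav("no sampled fiducial ids match the CT set",
                 "endonav_invalid_fiducials")
  if (anyNA(m)) {
    sampled <- sampled[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  if (length(m) < 3L)
    stop_endonav("fewer than 3 common fiducials", "endonav_invalid_fiducials")
  if (length(m) < length(fiducials_ct$ids))
    warning(sprintf("registering on %d of %d fiducials", length(m),
                    length(fiducials_ct$ids)))
  reg <- procrustes_register(fiducials_ct$points_ct[m, , drop = FALSE],
                             cbind(sampled$x_mm, sampled$y_mm, sampled$z_mm))
  list(patientref_from_ct = reg$transform, fre = reg$fre, n_used = length(m))
}

#' IR-tracked overlay chain
#'
#' Projects CT-frame targets through the dual-reference IR chain:
#' `endocam_from_endoref o inv(tracker_from_endoref) o
#' tracker_from_patientref o patientref_from_ct`. A frame in which either
#' body is invalid is skipped with an explicit status rather than projected.
#'
#' @param frame A `tracker_frame`.
#' @param endocam_from_endoref Hand-eye estimate.
#' @param patientref_from_ct Registration estimate.
#' @param intrinsics Endoscope `camera_intrinsics`.
#' @param targets_ct N x 3 CT-frame targets (mm).
#' @return List with `status` (`"ok"` or `"skipped"`), and when ok:
#'   `pixels`, `visible`, `endocam_from_ct` (the full chain).
#' @export
ir_overlay_chain <- function(frame, endocam_from_endoref, patientref_from_ct,
                             intrinsics, targets_ct) {
  if (!all(frame$valid))
    return(list(status = "skipped",
                invalid = names(frame$valid)[!frame$valid]))
  chain <- rt_compose(endocam_from_endoref,
                      rt_compose(rt_invert(frame$tracker_from_endoref),
                                 rt_compose(frame$tracker_from_patientref,
                                            patientref_from_ct)))
  pr <- project_points(intrinsics, chain, targets_ct)
  list(status = "ok", pixels = pr$pixels, visible = pr$visible,
       endocam_from_ct = chain)
}
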