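#' Rigid transforms in SE(3)
#'
#' A rigid transform is the universal currency of the navigation chains in
#' this package: every camera pose, board pose, tracker reading, registration
#' and hand-eye estimate is one. It is stored as a 3x3 rotation matrix plus a
#' translation vector in millimetres, and maps a point `x` (row vector, mm)
#' to `R x + t`. Points are row-per-point throughout the public interface.
#'
#' The constructor validates orthonormality and a positive determinant.
#' Inputs that are off by more than `1e-6` are rejected; smaller numerical
#' drift (as accumulates when composing long chains) is snapped to the
#' nearest rotation by polar projection, so every object held by the package
#' satisfies `t(R) %*% R == I` and `det(R) == 1` to better than `1e-9`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(rotation_about("z", 90), c(1, 2, 3))
#' rt_apply(t1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop_endonav("rotation must be a finite 3x3 matrix", "endonav_invalid_transform")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop_endonav("translation must be a finite length-3 vector",
                 "endonav_invalid_transform")
  dev <- max(abs(crossprod(rotation) - diag(3)))
  if (dev > 1e-6 || det(rotation) < 0)
    stop_endonav(sprintf(
      "rotation is not orthonormal with det +1 (deviation %.2e)", dev),
      "endonav_invalid_transform")
  if (dev > 1e-12) rotation <- project_to_rotation(rotation)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x Object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

check_transform <- function(t, what = "transform") {
  if (!is_rigid_transform(t))
    stop_endonav(sprintf("%s must be a rigid_transform", what),
                 "endonav_invalid_transform")
  t
}

# Nearest rotation in Frobenius norm (polar projection via SVD).
project_to_rotation <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) r <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  r
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` maps a point `x` to `a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  check_transform(a); check_transform(b)
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse transform.
#' @export
rt_invert <- function(t) {
  check_transform(t)
  rt <- t(t$rotation)
  rigid_transform(rt, -as.numeric(rt %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param points N x 3 matrix (or length-3 vector) of points in mm,
#'   row per point.
#' @return N x 3 matrix of transformed points.
#' @export
rt_apply <- function(t, points) {
  check_transform(t)
  points <- as_points_matrix(points)
  if (nrow(points) == 0L) return(points)
  out <- points %*% t(t$rotation)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  out[, 3] <- out[, 3] + t$translation[3]
  out
}

#' Rotation and translation distance between two poses
#'
#' The rotation error is the angle of the relative rotation `t(Ra) %*% Rb`
#' in degrees; the translation error is the Euclidean distance between the
#' translations in mm.
#'
#' @param a,b `rigid_transform` objects.
#' @return Named numeric vector `c(rotation_deg, translation_mm)`.
#' @export
pose_error <- function(a, b) {
  check_transform(a); check_transform(b)
  rel <- t(a$rotation) %*% b$rotation
  # atan2 form: numerically exact for small angles where acos((tr-1)/2)
  # loses half the significant digits
  cosang <- (sum(diag(rel)) - 1) / 2
  sinang <- sqrt(sum(c(rel[3, 2] - rel[2, 3], rel[1, 3] - rel[3, 1],
                       rel[2, 1] - rel[1, 2])^2)) / 2
  ang <- atan2(sinang, cosang) * 180 / pi
  c(rotation_deg = ang,
    translation_mm = sqrt(sum((a$translation - b$translation)^2)))
}

#' Rotation about a coordinate axis
#' @param axis One of `"x"`, `"y"`, `"z"`, or a length-3 axis vector.
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  rotvec_to_matrix(unit_vector(as.numeric(axis)) * angle_deg * pi / 180)
}

#' Rodrigues conversions between rotation vectors and matrices
#'
#' A rotation vector encodes axis * angle (radians).
#'
#' @param v Length-3 rotation vector (radians).
#' @return `rotvec_to_matrix`: 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(v) {
  v <- as.numeric(v)
  th <- sqrt(sum(v^2))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  if (th < 1e-12) return(diag(3) + K)  # first-order for tiny angles
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * (K %*% K)
}

#' @rdname rotvec_to_matrix
#' @param r 3x3 rotation matrix.
#' @return `matrix_to_rotvec`: length-3 rotation vector (radians).
#' @export
matrix_to_rotvec <- function(r) {
  cosang <- (sum(diag(r)) - 1) / 2
  th <- acos(min(1, max(-1, cosang)))
  if (th < 1e-12) {
    return(c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near pi: extract axis from R + I
    m <- (r + diag(3)) / 2
    axis <- sqrt(pmax(diag(m), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    if (i == 1L) axis <- axis * sign(c(1, m[1, 2], m[1, 3]) + (c(1, m[1, 2], m[1, 3]) == 0))
    if (i == 2L) axis <- axis * sign(c(m[1, 2], 1, m[2, 3]) + (c(m[1, 2], 1, m[2, 3]) == 0))
    if (i == 3L) axis <- axis * sign(c(m[1, 3], m[2, 3], 1) + (c(m[1, 3], m[2, 3], 1) == 0))
    return(unit_vector(axis) * th)
  }
  axis <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) / (2 * sin(th))
  axis * th
}

#' Draw a random rigid transform within bounds
#'
#' Rotation axis and translation direction are uniform on the sphere; the
#' rotation angle and translation magnitude are uniform on
#' `[0, max_rotation_deg]` and `[0, max_translation_mm]`. Deterministic for a
#' given seed.
#'
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param max_rotation_deg,max_translation_mm Non-negative bounds.
#' @return A `rigid_transform`.
#' @export
random_pose <- function(seed = NULL, max_rotation_deg = 30,
                        max_translation_mm = 50) {
  stopifnot(max_rotation_deg >= 0, max_translation_mm >= 0)
  with_seed(seed, {
    ang <- runif(1, 0, max_rotation_deg)
    rot <- if (ang == 0) diag(3) else
      rotvec_to_matrix(random_unit_vector() * ang * pi / 180)
    mag <- runif(1, 0, max_translation_mm)
    tr <- if (mag == 0) c(0, 0, 0) else random_unit_vector() * mag
    rigid_transform(rot, tr)
  })
}

random_unit_vector <- function() unit_vector(rnorm(3))

#' Perturb a pose by a fixed-magnitude offset
#'
#' Composes `t` on the right with a rotation of exactly `rot_deg` about a
#' random axis and a translation of exactly `trans_mm` in a random direction
#' (i.e. the perturbation is expressed in the pose's own frame). Used for
#' prior offsets and injected calibration errors of stated size.
#'
#' @param t Pose to perturb.
#' @param rot_deg,trans_mm Offset magnitudes.
#' @param seed Optional seed.
#' @return Perturbed `rigid_transform`.
#' @export
perturb_pose <- function(t, rot_deg, trans_mm, seed = NULL) {
  check_transform(t)
  with_seed(seed, {
    rot <- if (rot_deg == 0) diag(3) else
      rotvec_to_matrix(random_unit_vector() * rot_deg * pi / 180)
    tr <- if (trans_mm == 0) c(0, 0, 0) else random_unit_vector() * trans_mm
    rt_compose(t, rigid_transform(rot, tr))
  })
}

#' Gaussian pose noise for tracked bodies
#'
#' Returns `t` composed on the right with a noise pose: the angular
#' perturbation magnitude is half-normal with mean `rot_mean_abs_deg` about a
#' random axis, and the translation is isotropic Gaussian scaled so that the
#' RMS of the 3D displacement norm is `trans_rms_mm`. These conventions (mean
#' absolute angle, RMS norm) match how tracker vendors quote pose noise.
#'
#' @param t Pose to perturb.
#' @param rot_mean_abs_deg Mean absolute angular perturbation (degrees).
#' @param trans_rms_mm RMS of the translational perturbation norm (mm).
#' @param seed Optional seed.
#' @return Noisy `rigid_transform`.
#' @export
pose_noise <- function(t, rot_mean_abs_deg, trans_rms_mm, seed = NULL) {
  check_transform(t)
  with_seed(seed, {
    # E|N(0, s)| = s * sqrt(2/pi)  =>  s = mean_abs * sqrt(pi/2)
    ang <- abs(rnorm(1, 0, rot_mean_abs_deg * sqrt(pi / 2)))
    rot <- if (rot_mean_abs_deg == 0) diag(3) else
      rotvec_to_matrix(random_unit_vector() * ang * pi / 180)
    # E||N(0, s I3)||^2 = 3 s^2  =>  s = rms / sqrt(3)
    tr <- rnorm(3, 0, trans_rms_mm / sqrt(3))
    rt_compose(t, rigid_transform(rot, tr))
  })
}

#' Camera pose looking at a target point
#'
#' Builds `camera_from_world` for a camera at `eye` whose +z axis points at
#' `target`, with image +y roughly opposite `up`.
#'
#' @param eye,target Length-3 points (mm, world frame).
#' @param up Approximate world up direction.
#' @return `rigid_transform` mapping world to camera coordinates.
#' @export
look_at <- function(eye, target, up = c(0, 0, 1)) {
  z <- unit_vector(as.numeric(target) - as.numeric(eye))
  x <- unit_vector(cross3(as.numeric(up), z))
  y <- cross3(z, x)
  r_wc <- cbind(x, y, z)  # world_from_camera rotation
  rt_invert(rigid_transform(r_wc, as.numeric(eye)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- pose_error(rt_identity(), rigid_transform(x$rotation))["rotation_deg"]
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Convert between rigid transforms and 4x4 homogeneous matrices
#' @param t A `rigid_transform`.
#' @return `rt_to_matrix4`: 4x4 homogeneous matrix.
#' @export
rt_to_matrix4 <- function(t) {
  check_transform(t)
  rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
}

#' @rdname rt_to_matrix4
#' @param m 4x4 homogeneous matrix with bottom row `(0, 0, 0, 1)`.
#' @export
rt_from_matrix4 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L)))
    stop_endonav("expected a 4x4 matrix", "endonav_invalid_transform")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop_endonav("bottom row of a homogeneous transform must be (0,0,0,1)",
                 "endonav_invalid_transform")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Read and write rigid transforms as JSON
#'
#' Schema: `{"units": "mm", "matrix": [[...4x4...]]}`. The reader rejects any
#' units other than `"mm"` and validates the bottom row.
#'
#' @param t A `rigid_transform`.
#' @param path File path.
#' @export
write_transform_json <- function(t, path) {
  m <- rt_to_matrix4(t)
  jsonlite::write_json(list(units = "mm", matrix = m), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @return `read_transform_json`: a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$units, "mm"))
    stop_endonav(sprintf("transform file '%s' must declare units \"mm\"", path),
                 "endonav_units_error")
  rt_from_matrix4(obj$matrix)
}
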