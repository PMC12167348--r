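# Planar calibration: homographies, Zhang intrinsics, planar pose.

# DLT homography with Hartley normalization, mapping src (N x 2) to dst (N x 2).
homography_dlt <- function(src, dst) {
  n <- nrow(src)
  if (n < 4L) stop_endonav("homography needs >= 4 points", "endonav_degenerate")
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums((p - rep(ctr, each = nrow(p)))^2))
    s <- sqrt(2) / max(mean(d), 1e-12)
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(T = T, p = cbind(p[, 1] * s - s * ctr[1], p[, 2] * s - s * ctr[2]))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- svd(A)
  if (sv$d[8] / max(sv$d[1], 1e-300) < 1e-10)
    stop_endonav("homography is rank deficient (collinear points?)",
                 "endonav_degenerate")
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

zhang_v <- function(H, i, j) {
  c(H[1, i] * H[1, j],
    H[1, i] * H[2, j] + H[2, i] * H[1, j],
    H[2, i] * H[2, j],
    H[3, i] * H[1, j] + H[1, i] * H[3, j],
    H[3, i] * H[2, j] + H[2, i] * H[3, j],
    H[3, i] * H[3, j])
}

#' Zhang planar intrinsic calibration
#'
#' Closed-form intrinsics from the homography constraints on the image of
#' the absolute conic, followed (optionally) by joint Levenberg-Marquardt
#' refinement of intrinsics, distortion and per-view poses minimizing pixel
#' reprojection error. Skew is held at zero during refinement.
#'
#' @param board A `marker_board`.
#' @param detections List of `board_detection`s, one per view, each with at
#'   least 4 non-collinear points; at least 3 views in general pose.
#' @param width,height Image size of the calibrated camera (px).
#' @param refine Run the nonlinear refinement (default `TRUE`).
#' @return List with `intrinsics` (`camera_intrinsics`), `view_rms` (px,
#'   post-refinement when `refine`), `rms` (overall px RMS), and `poses`
#'   (per-view `camera_from_board` transforms).
#' @export
calibrate_intrinsics_zhang <- function(board, detections, width, height,
                                       refine = TRUE) {
  if (length(detections) < 3L)
    stop_endonav(sprintf("Zhang calibration needs >= 3 views, got %d",
                         length(detections)), "endonav_insufficient_views")
  views <- lapply(detections, function(det) {
    m <- match(det$point_ids, board$points$id)
    if (anyNA(m))
      stop_endonav("detection references point ids not on the board",
                   "endonav_invalid_detection")
    obj <- cbind(board$points$x_mm[m], board$points$y_mm[m])
    if (nrow(obj) < 4L || is_collinear_2d(obj))
      stop_endonav("each view needs >= 4 non-collinear board points",
                   "endonav_degenerate")
    list(obj = obj, px = det$pixels)
  })
  Hs <- lapply(views, function(v) homography_dlt(v$obj, v$px))
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(zhang_v(H, 1, 2), zhang_v(H, 1, 1) - zhang_v(H, 2, 2))
  }))
  sv <- svd(V)
  if (sv$d[5] / max(sv$d[1], 1e-300) < 1e-12)
    stop_endonav("degenerate view configuration for Zhang calibration",
                 "endonav_degenerate")
  b <- sv$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  if (abs(den) < 1e-300 || abs(B11) < 1e-300)
    stop_endonav("degenerate view configuration for Zhang calibration",
                 "endonav_degenerate")
  v0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  if (lam / B11 <= 0 || lam / den * B11 <= 0)
    stop_endonav("degenerate view configuration for Zhang calibration",
                 "endonav_degenerate")
  alpha <- sqrt(lam / B11)
  beta <- sqrt(lam * B11 / den)
  gamma <- -B12 * alpha^2 * beta / lam
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lam
  intr <- camera_intrinsics(alpha, beta,
                            min(max(u0, 0), width - 1e-9),
                            min(max(v0, 0), height - 1e-9),
                            width, height, skew = 0)
  K <- matrix(c(alpha, 0, 0, gamma, beta, 0, u0, v0, 1), 3, 3)
  poses <- lapply(Hs, function(H) planar_pose_from_homography(solve(K) %*% H))
  if (refine) {
    # parameters: fx fy cx cy k1 k2 p1 p2 k3, then (rvec, tvec) per view
    pose_par <- unlist(lapply(poses, function(p)
      c(matrix_to_rotvec(p$rotation), p$translation)))
    par0 <- c(alpha, beta, u0, v0, rep(0, 5), pose_par)
    resid <- function(par) {
      intr_i <- tryCatch(
        camera_intrinsics(par[1], par[2], par[3], par[4], width, height,
                          dist = par[5:9]),
        error = function(e) NULL)
      if (is.null(intr_i)) return(rep(1e6, 2 * sum(vapply(views, function(v)
        nrow(v$px), 1L))))
      unlist(lapply(seq_along(views), function(i) {
        p6 <- par[9 + (i - 1) * 6 + 1:6]
        pose <- rigid_transform(rotvec_to_matrix(p6[1:3]), p6[4:6])
        obj3 <- cbind(views[[i]]$obj, 0)
        pr <- project_points(intr_i, pose, obj3)
        as.numeric(pr$pixels - views[[i]]$px)
      }))
    }
    fit <- lm_least_squares(par0, resid, max_iter = 100L, tol = 1e-12)
    par <- fit$par
    intr <- camera_intrinsics(par[1], par[2], par[3], par[4], width, height,
                              dist = par[5:9])
    poses <- lapply(seq_along(views), function(i) {
      p6 <- par[9 + (i - 1) * 6 + 1:6]
      rigid_transform(rotvec_to_matrix(p6[1:3]), p6[4:6])
    })
  }
  view_rms <- vapply(seq_along(views), function(i) {
    pr <- project_points(intr, poses[[i]], cbind(views[[i]]$obj, 0))
    sqrt(mean(rowSums((pr$pixels - views[[i]]$px)^2)))
  }, 0)
  npts <- vapply(views, function(v) nrow(v$px), 1L)
  list(intrinsics = intr, view_rms = view_rms,
       rms = sqrt(sum(view_rms^2 * npts) / sum(npts)), poses = poses)
}

is_collinear_2d <- function(p, tol = 1e-8) {
  p <- sweep(p, 2, colMeans(p))
  d <- svd(p, nu = 0, nv = 0)$d
  d[2] <= tol * max(d[1], 1e-12)
}

# Orthonormalized pose from a normalized-coordinate homography
# (H maps board-plane mm to undistorted normalized coordinates).
planar_pose_from_homography <- function(H) {
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lam <- 2 / (sqrt(sum(h1^2)) + sqrt(sum(h2^2)))
  r1 <- lam * h1; r2 <- lam * h2
  t <- lam * h3
  if (t[3] < 0) {  # board must lie in front of the camera
    r1 <- -r1; r2 <- -r2; t <- -t
  }
  R <- project_to_rotation(cbind(r1, r2, cross3(r1, r2)))
  rigid_transform(R, t)
}

#' Planar pose from board-to-pixel correspondences
#'
#' Homography-based planar pose: pixels are undistorted to normalized
#' coordinates, a DLT homography against the board plane is decomposed into
#' an orthonormalized pose (the sign ambiguity resolved by requiring the
#' board in front of the camera), then the pose is refined by
#' Levenberg-Marquardt on pixel reprojection error. Refinement never
#' increases the reprojection RMS.
#'
#' @param intrinsics A `camera_intrinsics`.
#' @param object_xy N x 2 board-plane coordinates (mm), N >= 4, non-collinear.
#' @param pixels N x 2 observed pixels.
#' @param refine Run LM refinement (default `TRUE`).
#' @return List with `transform` (`camera_from_board`) and `rms` (px).
#' @export
estimate_planar_pose <- function(intrinsics, object_xy, pixels, refine = TRUE) {
  check_intrinsics(intrinsics)
  object_xy <- as.matrix(object_xy)
  pixels <- as.matrix(pixels)
  if (nrow(object_xy) < 4L)
    stop_endonav("planar pose needs >= 4 correspondences", "endonav_degenerate")
  if (is_collinear_2d(object_xy))
    stop_endonav("planar pose needs non-collinear points", "endonav_degenerate")
  nrm <- pixel_to_normalized(intrinsics, pixels)
  H <- homography_dlt(object_xy, nrm)
  pose <- planar_pose_from_homography(H)
  obj3 <- cbind(object_xy, 0)
  rms_of <- function(p) {
    pr <- project_points(intrinsics, p, obj3)
    sqrt(mean(rowSums((pr$pixels - pixels)^2)))
  }
  if (refine) {
    par0 <- c(matrix_to_rotvec(pose$rotation), pose$translation)
    resid <- function(par) {
      p <- rigid_transform(rotvec_to_matrix(par[1:3]), par[4:6])
      pr <- project_points(intrinsics, p, obj3)
      as.numeric(pr$pixels - pixels)
    }
    fit <- lm_least_squares(par0, resid, max_iter = 100L, tol = 1e-12)
    cand <- rigid_transform(rotvec_to_matrix(fit$par[1:3]), fit$par[4:6])
    if (rms_of(cand) <= rms_of(pose)) pose <- cand
  }
  list(transform = pose, rms = rms_of(pose))
}
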