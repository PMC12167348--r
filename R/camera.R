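#' Pinhole camera intrinsics with Brown-Conrady distortion
#'
#' Focal lengths and principal point are in pixels; distortion follows the
#' 5-coefficient Brown-Conrady model `(k1, k2, p1, p2, k3)` applied in
#' normalized image coordinates, the convention used by mainstream
#' calibration toolchains.
#'
#' @param fx,fy Focal lengths (px), positive.
#' @param cx,cy Principal point (px), inside the image.
#' @param width,height Image size (px).
#' @param skew Skew term (px), default 0.
#' @param dist Length-5 distortion vector `(k1, k2, p1, p2, k3)`.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height, skew = 0,
                              dist = c(0, 0, 0, 0, 0)) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop_endonav("principal point must lie inside the image",
                 "endonav_invalid_intrinsics")
  dist <- as.numeric(dist)
  if (length(dist) != 5L)
    stop_endonav("dist must be (k1, k2, p1, p2, k3)", "endonav_invalid_intrinsics")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
                 dist = dist, width = as.integer(width),
                 height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %dx%d px, f = (%.2f, %.2f), c = (%.2f, %.2f)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  cat(sprintf("  dist (k1,k2,p1,p2,k3) = %s\n",
              paste(signif(x$dist, 4), collapse = ", ")))
  invisible(x)
}

check_intrinsics <- function(intr) {
  if (!inherits(intr, "camera_intrinsics"))
    stop_endonav("expected a camera_intrinsics object", "endonav_invalid_intrinsics")
  intr
}

# Apply Brown-Conrady distortion to normalized coordinates (N x 2).
distort_normalized <- function(intr, xy) {
  k <- intr$dist
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + k[1] * r2 + k[2] * r2^2 + k[5] * r2^3
  xd <- x * radial + 2 * k[3] * x * y + k[4] * (r2 + 2 * x^2)
  yd <- y * radial + k[3] * (r2 + 2 * y^2) + 2 * k[4] * x * y
  cbind(xd, yd)
}

# Invert the distortion by fixed-point iteration (20 iterations or 1e-10).
undistort_normalized <- function(intr, xy) {
  if (all(intr$dist == 0)) return(xy)
  out <- xy
  for (i in 1:20) {
    d <- distort_normalized(intr, out)
    delta <- xy - d
    out <- out + delta
    if (max(abs(delta)) < 1e-10) break
  }
  out
}

#' Project world points into a camera image
#'
#' Standard pinhole projection with distortion. Points behind the camera or
#' projecting outside the image are flagged not-visible rather than raising
#' an error.
#'
#' @param intrinsics A `camera_intrinsics`.
#' @param camera_from_world `rigid_transform` mapping world to camera frame.
#' @param points N x 3 matrix of world points (mm).
#' @return List with `pixels` (N x 2), `visible` (logical N), `depth`
#'   (camera-frame z, mm).
#' @export
project_points <- function(intrinsics, camera_from_world, points) {
  check_intrinsics(intrinsics)
  check_transform(camera_from_world)
  pc <- rt_apply(camera_from_world, points)
  n <- nrow(pc)
  if (n == 0L)
    return(list(pixels = matrix(0, 0, 2), visible = logical(0), depth = numeric(0)))
  z <- pc[, 3]
  infront <- z > 1e-9
  xn <- ifelse(infront, pc[, 1] / z, NA_real_)
  yn <- ifelse(infront, pc[, 2] / z, NA_real_)
  d <- matrix(NA_real_, n, 2)
  ok <- which(infront)
  if (length(ok)) d[ok, ] <- distort_normalized(intrinsics, cbind(xn[ok], yn[ok]))
  u <- intrinsics$fx * d[, 1] + intrinsics$skew * d[, 2] + intrinsics$cx
  v <- intrinsics$fy * d[, 2] + intrinsics$cy
  visible <- infront & !is.na(u) & !is.na(v) &
    u >= 0 & u < intrinsics$width & v >= 0 & v < intrinsics$height
  list(pixels = cbind(u = u, v = v), visible = visible, depth = z)
}

#' Convert pixels to undistorted normalized image coordinates
#' @param intrinsics A `camera_intrinsics`.
#' @param pixels N x 2 pixel coordinates.
#' @return N x 2 normalized coordinates.
#' @export
pixel_to_normalized <- function(intrinsics, pixels) {
  check_intrinsics(intrinsics)
  pixels <- as.matrix(pixels)
  if (is.null(dim(pixels)) || ncol(pixels) != 2L)
    pixels <- matrix(pixels, ncol = 2L)
  yd <- (pixels[, 2] - intrinsics$cy) / intrinsics$fy
  xd <- (pixels[, 1] - intrinsics$cx - intrinsics$skew * yd) / intrinsics$fx
  undistort_normalized(intrinsics, cbind(xd, yd))
}

#' Depth maps
#'
#' A depth map stores one z-depth (mm) per pixel in a `height x width`
#' matrix; zero marks an invalid pixel. The intrinsics of the capturing
#' camera travel with the map so it can be back-projected.
#'
#' @param depth `height x width` numeric matrix of z-depths (mm, 0 invalid).
#' @param intrinsics The capturing camera's `camera_intrinsics`.
#' @return An object of class `depth_map`.
#' @export
depth_map <- function(depth, intrinsics) {
  check_intrinsics(intrinsics)
  depth <- as.matrix(depth)
  if (nrow(depth) != intrinsics$height || ncol(depth) != intrinsics$width)
    stop_endonav("depth matrix dimensions must match intrinsics",
                 "endonav_invalid_depth")
  vals <- depth[depth != 0]
  if (length(vals) && (!all(is.finite(vals)) || any(vals < 0)))
    stop_endonav("valid depths must be strictly positive and finite",
                 "endonav_invalid_depth")
  structure(list(depth = depth, intrinsics = intrinsics), class = "depth_map")
}

#' Back-project a depth map to a camera-frame point cloud
#'
#' One 3D point per valid pixel via the inverse (distortion-corrected)
#' pinhole model: pixel `(u, v)` with depth `z` maps to
#' `z * (xn, yn, 1)` where `(xn, yn)` are its undistorted normalized
#' coordinates. An all-invalid map yields an empty cloud.
#'
#' @param dm A `depth_map`.
#' @return A `point_cloud` in the camera frame (mm).
#' @export
backproject_depth <- function(dm) {
  if (!inherits(dm, "depth_map")) stop_endonav("expected a depth_map",
                                               "endonav_invalid_depth")
  valid <- which(dm$depth != 0, arr.ind = TRUE)
  if (nrow(valid) == 0L) {
    cl <- point_cloud(matrix(0, 0, 3))
    attr(cl, "empty") <- TRUE
    return(cl)
  }
  # pixel coordinates: column index -> u, row index -> v (0-based grid)
  u <- valid[, 2] - 1
  v <- valid[, 1] - 1
  z <- dm$depth[valid]
  nrm <- pixel_to_normalized(dm$intrinsics, cbind(u, v))
  point_cloud(cbind(nrm[, 1] * z, nrm[, 2] * z, z))
}

#' Read and write camera intrinsics as JSON
#'
#' Schema: `{"units":"px","fx":..,"fy":..,"cx":..,"cy":..,"skew":0,
#' "dist":[k1,k2,p1,p2,k3],"width":..,"height":..}`.
#'
#' @param intr A `camera_intrinsics`.
#' @param path File path.
#' @export
write_intrinsics_json <- function(intr, path) {
  check_intrinsics(intr)
  jsonlite::write_json(
    list(units = "px", fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
         skew = intr$skew, dist = intr$dist, width = intr$width,
         height = intr$height),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_intrinsics_json
#' @return `read_intrinsics_json`: a `camera_intrinsics`.
#' @export
read_intrinsics_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$units, "px"))
    stop_endonav("intrinsics file must declare units \"px\"", "endonav_units_error")
  camera_intrinsics(o$fx, o$fy, o$cx, o$cy, o$width, o$height,
                    skew = o$skew %||% 0, dist = o$dist)
}

#' Read and write depth maps as integer-grid text with a JSON sidecar
#'
#' The grid is written as a plain-text matrix of 16-bit integers (depth
#' divided by `scale_mm`, rounded); the sidecar (`<path>.json`) carries the
#' scale and the capturing intrinsics. The integer grid round-trips
#' bit-exactly; absolute depths are quantized at `scale_mm`.
#'
#' @param dm A `depth_map`.
#' @param path Grid file path (sidecar written alongside).
#' @param scale_mm Millimetres per integer unit.
#' @export
write_depth_map <- function(dm, path, scale_mm = 0.05) {
  ints <- round(dm$depth / scale_mm)
  if (any(ints > 65535))
    stop_endonav("depth exceeds 16-bit range at this scale", "endonav_invalid_depth")
  write.table(ints, path, row.names = FALSE, col.names = FALSE)
  write_intrinsics_json(dm$intrinsics, paste0(path, ".json"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  side$scale_mm <- scale_mm
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_depth_map
#' @return `read_depth_map`: a `depth_map`.
#' @export
read_depth_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  intr <- camera_intrinsics(side$fx, side$fy, side$cx, side$cy, side$width,
                            side$height, skew = side$skew %||% 0,
                            dist = side$dist)
  ints <- as.matrix(read.table(path))
  dimnames(ints) <- NULL
  depth_map(ints * side$scale_mm, intr)
}
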