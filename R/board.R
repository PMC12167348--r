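#' Planar marker boards
#'
#' A marker board is reduced to its geometry: the interior chessboard
#' corners of a `rows x cols` board with squares of `square_mm`, i.e. a
#' `(rows-1) x (cols-1)` grid of identified 2D points on the z = 0 board
#' plane with the origin at the board corner. Marker decoding happens in
#' simulation, so only this geometry matters.
#'
#' @param rows,cols Number of squares along each side (both >= 2).
#' @param square_mm Square side length (mm), positive.
#' @param id Board identifier string.
#' @return An object of class `marker_board` with a `points` data frame
#'   (`id`, `x_mm`, `y_mm`).
#' @examples
#' b <- make_board(5, 9, 20)   # 4 x 8 = 32 interior corners
#' nrow(b$points)
#' @export
make_board <- function(rows, cols, square_mm, id = "board") {
  if (rows < 2 || cols < 2 || square_mm <= 0)
    stop_endonav("board needs rows >= 2, cols >= 2, square_mm > 0",
                 "endonav_invalid_board")
  g <- expand.grid(ix = seq_len(cols - 1) - 1L, iy = seq_len(rows - 1) - 1L)
  pts <- data.frame(id = seq_len(nrow(g)),
                    x_mm = g$ix * square_mm,
                    y_mm = g$iy * square_mm)
  structure(list(board_id = id, rows = rows, cols = cols,
                 square_mm = square_mm, points = pts),
            class = "marker_board")
}

#' @export
print.marker_board <- function(x, ...) {
  cat(sprintf("<marker_board '%s'> %dx%d squares of %g mm, %d corner points\n",
              x$board_id, x$rows, x$cols, x$square_mm, nrow(x$points)))
  invisible(x)
}

#' Board corner observations in one camera frame
#'
#' @param frame Frame index.
#' @param point_ids Integer ids of the observed board points.
#' @param pixels N x 2 pixel coordinates.
#' @param camera_id Capturing camera identifier.
#' @param board A `marker_board` the ids refer to (optional, enables id
#'   validation).
#' @return An object of class `board_detection`.
#' @export
board_detection <- function(frame, point_ids, pixels, camera_id = "camera",
                            board = NULL) {
  pixels <- as.matrix(pixels)
  if (length(point_ids) != nrow(pixels))
    stop_endonav("one pixel row per point id required", "endonav_invalid_detection")
  if (nrow(pixels) && !all(is.finite(pixels)))
    stop_endonav("pixel coordinates must be finite", "endonav_invalid_detection")
  if (!is.null(board) && length(point_ids) &&
      !all(point_ids %in% board$points$id))
    stop_endonav("detection references point ids not on the board",
                 "endonav_invalid_detection")
  structure(list(frame = frame, camera_id = camera_id,
                 point_ids = as.integer(point_ids), pixels = pixels),
            class = "board_detection")
}

#' Estimate a board pose from a (possibly partial) detection
#'
#' Matches detected point ids against the board layout and delegates to
#' [estimate_planar_pose()]. Succeeds whenever at least `min_points`
#' non-collinear points were detected — this is what makes the board usable
#' as a patient reference under partial occlusion.
#'
#' @param intrinsics A `camera_intrinsics`.
#' @param board A `marker_board`.
#' @param detection A `board_detection` referring to this board.
#' @param min_points Minimum usable points (>= 4).
#' @return List with `transform` (`camera_from_board`), `rms` (px),
#'   `n_points` used.
#' @export
board_pose_from_detection <- function(intrinsics, board, detection,
                                      min_points = 4L) {
  if (min_points < 4L)
    stop_endonav("min_points must be >= 4 for planar pose", "endonav_invalid_board")
  m <- match(detection$point_ids, board$points$id)
  if (anyNA(m))
    stop_endonav("detection references point ids not on the board",
                 "endonav_invalid_detection")
  if (length(m) < min_points)
    stop_endonav(sprintf("insufficient markers: %d detected, %d required",
                         length(m), min_points),
                 "endonav_insufficient_markers")
  obj <- cbind(board$points$x_mm[m], board$points$y_mm[m])
  est <- estimate_planar_pose(intrinsics, obj, detection$pixels)
  list(transform = est$transform, rms = est$rms, n_points = length(m))
}

#' Read and write board definitions as YAML
#' @param board A `marker_board`.
#' @param path File path.
#' @export
write_board_yaml <- function(board, path) {
  yaml::write_yaml(list(board_id = board$board_id, rows = board$rows,
                        cols = board$cols, square_mm = board$square_mm), path)
  invisible(path)
}

#' @rdname write_board_yaml
#' @return `read_board_yaml`: a `marker_board`.
#' @export
read_board_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  make_board(o$rows, o$cols, o$square_mm, id = o$board_id %||% "board")
}

#' Read and write detections as CSV (frame, camera, point_id, u_px, v_px)
#' @param detections List of `board_detection` objects.
#' @param path File path.
#' @export
write_detections_csv <- function(detections, path) {
  if (inherits(detections, "board_detection")) detections <- list(detections)
  rows <- do.call(rbind, lapply(detections, function(d) {
    data.frame(frame = d$frame, camera = d$camera_id, point_id = d$point_ids,
               u_px = d$pixels[, 1], v_px = d$pixels[, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @return `read_detections_csv`: list of `board_detection` objects, one per
#'   (frame, camera) pair.
#' @export
read_detections_csv <- function(path) {
  d <- read.csv(path)
  keys <- unique(d[, c("frame", "camera")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$frame == keys$frame[i] & d$camera == keys$camera[i], ]
    board_detection(keys$frame[i], sub$point_id, cbind(sub$u_px, sub$v_px),
                    camera_id = keys$camera[i])
  })
}
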