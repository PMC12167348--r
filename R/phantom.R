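#' Parameters of the synthetic phantom
#'
#' The phantom stands in for a physical surgical training head: a smooth
#' half-ellipsoid "face" with a nose-like ridge, a regular grid of spherical
#' targets in an interior plane, and seven fiducial markers along the base
#' perimeter. All geometry is parametric (no scanned model is shipped), so
#' every geometric claim is a property of this generator.
#'
#' @param half_axes Ellipsoid half-axes (x, y, z) in mm.
#' @param nose_amp Nose ridge amplitude (mm).
#' @param nose_center Ridge centre in the (x, y) base plane (mm).
#' @param nose_sigma Ridge Gaussian widths (x, y) in mm.
#' @param rings,slices Mesh resolution (radial rings, angular slices).
#' @param grid_dims Target grid dimensions (nx, ny).
#' @param grid_pitch_mm Target spacing (mm); the published phantom uses a
#'   1 cm grid.
#' @param grid_z Height of the target plane above the base (mm).
#' @param grid_center Grid centre in the (x, y) plane (mm).
#' @param n_fiducials Number of base fiducials (the published setup uses 7).
#' @param fid_radius_frac Fiducial ring radius as a fraction of the base
#'   ellipse.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(half_axes = c(90, 70, 110), nose_amp = 12,
                           nose_center = c(0, -35), nose_sigma = c(14, 22),
                           rings = 24L, slices = 48L,
                           grid_dims = c(5L, 5L), grid_pitch_mm = 10,
                           grid_z = 40, grid_center = c(0, -10),
                           n_fiducials = 7L, fid_radius_frac = 0.92) {
  if (any(half_axes <= 0)) stop_endonav("half axes must be positive",
                                        "endonav_invalid_phantom")
  if (any(grid_dims < 1L)) stop_endonav("grid dimensions must be >= 1x1",
                                        "endonav_invalid_phantom")
  structure(list(half_axes = half_axes, nose_amp = nose_amp,
                 nose_center = nose_center, nose_sigma = nose_sigma,
                 rings = as.integer(rings), slices = as.integer(slices),
                 grid_dims = as.integer(grid_dims),
                 grid_pitch_mm = grid_pitch_mm, grid_z = grid_z,
                 grid_center = grid_center,
                 n_fiducials = as.integer(n_fiducials),
                 fid_radius_frac = fid_radius_frac),
            class = "phantom_params")
}

face_height <- function(params, x, y, r2 = NULL) {
  a <- params$half_axes[1]; b <- params$half_axes[2]; c3 <- params$half_axes[3]
  if (is.null(r2)) r2 <- (x / a)^2 + (y / b)^2
  z <- c3 * sqrt(pmax(0, 1 - r2))
  bump <- params$nose_amp *
    exp(-((x - params$nose_center[1]) / params$nose_sigma[1])^2 -
          ((y - params$nose_center[2]) / params$nose_sigma[2])^2)
  z + bump * pmax(0, 1 - r2)
}

#' Build a synthetic phantom
#'
#' Generates the face mesh (closed: domed top plus base disk), the target
#' grid, the base fiducials, and the mounting transforms. Deterministic for
#' a given seed.
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed (the default geometry is deterministic; the seed
#'   is threaded through for forward compatibility of stochastic variants).
#' @param ct_from_board Mounting pose of the tracked fiducial board in the
#'   CT frame (board coordinates to CT coordinates).
#' @param world_from_ct Pose of the phantom (holder) in the world frame.
#' @return A `phantom_model` with fields `face` (`surface_mesh`), `targets`
#'   (M x 3 mm, CT frame), `fiducials` (data frame id, x_mm, y_mm, z_mm),
#'   `ct_from_board`, `world_from_ct`, `params`.
#' @export
make_phantom <- function(params = phantom_params(), seed = 0L,
                         ct_from_board = default_board_mount(),
                         world_from_ct = default_holder_pose()) {
  a <- params$half_axes[1]; b <- params$half_axes[2]
  nr <- params$rings; na <- params$slices
  theta <- seq(0, 2 * pi, length.out = na + 1L)[-(na + 1L)]
  verts <- matrix(0, 1L + nr * na, 3)
  verts[1L, ] <- c(0, 0, face_height(params, 0, 0))
  for (i in seq_len(nr)) {
    r <- i / nr
    x <- a * r * cos(theta); y <- b * r * sin(theta)
    rows <- 1L + (i - 1L) * na + seq_len(na)
    verts[rows, ] <- cbind(x, y, face_height(params, x, y))
  }
  vid <- function(i, j) {  # ring i (1..nr), slice j (wraps)
    1L + (i - 1L) * na + ((j - 1L) %% na) + 1L
  }
  faces <- list()
  # apex fan (CCW seen from +z outside)
  for (j in seq_len(na)) faces[[length(faces) + 1L]] <- c(1L, vid(1L, j), vid(1L, j + 1L))
  # quads between rings
  for (i in seq_len(nr - 1L)) for (j in seq_len(na)) {
    v00 <- vid(i, j); v01 <- vid(i, j + 1L)
    v10 <- vid(i + 1L, j); v11 <- vid(i + 1L, j + 1L)
    faces[[length(faces) + 1L]] <- c(v00, v10, v11)
    faces[[length(faces) + 1L]] <- c(v00, v11, v01)
  }
  # base disk (normal -z): centre vertex + fan over boundary ring
  base_centre <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, 0))
  for (j in seq_len(na))
    faces[[length(faces) + 1L]] <- c(base_centre, vid(nr, j + 1L), vid(nr, j))
  face <- surface_mesh(verts, do.call(rbind, faces))

  gx <- (seq_len(params$grid_dims[1]) - (params$grid_dims[1] + 1) / 2) *
    params$grid_pitch_mm + params$grid_center[1]
  gy <- (seq_len(params$grid_dims[2]) - (params$grid_dims[2] + 1) / 2) *
    params$grid_pitch_mm + params$grid_center[2]
  g <- expand.grid(x = gx, y = gy)
  targets <- cbind(g$x, g$y, rep(params$grid_z, nrow(g)))

  ang <- seq(0, 2 * pi, length.out = params$n_fiducials + 1L)[-(params$n_fiducials + 1L)]
  ang <- ang + 0.17  # break symmetry so no fiducial sits on an axis
  fid <- data.frame(id = seq_len(params$n_fiducials),
                    x_mm = params$fid_radius_frac * a * cos(ang),
                    y_mm = params$fid_radius_frac * b * sin(ang),
                    z_mm = 0)
  structure(list(face = face, targets = targets, fiducials = fid,
                 ct_from_board = check_transform(ct_from_board),
                 world_from_ct = check_transform(world_from_ct),
                 params = params, seed = seed),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf(paste0("<phantom_model> %d-vertex face mesh, %d targets at ",
                     "%g mm pitch, %d fiducials\n"),
              nrow(x$face$vertices), nrow(x$targets),
              x$params$grid_pitch_mm, nrow(x$fiducials)))
  invisible(x)
}

#' Default mounting transforms of the synthetic scene
#'
#' The tracked board sits on the holder beside the head, tilted so its
#' normal faces the on-board camera's working position; the holder pose
#' keeps the world frame distinct from the CT frame so frame bookkeeping
#' bugs cannot hide.
#'
#' @return A `rigid_transform`.
#' @export
default_board_mount <- function() {
  z <- unit_vector(c(-0.25, -0.55, 0.8))   # board normal towards the camera
  x <- unit_vector(cross3(c(0, 1, 0), z))
  rigid_transform(cbind(x, cross3(z, x), z), c(110, -75, 15))
}

#' @rdname default_board_mount
#' @export
default_holder_pose <- function() {
  rigid_transform(rotation_about("z", 7), c(15, -10, 5))
}

#' Derive the CT surface model handed to the registration pipeline
#'
#' Models CT acquisition, segmentation and smoothing as a vertex-jittered
#' (and optionally re-meshed) copy of the true face surface, so the
#' CT-versus-reality discrepancy of a real scan is representable.
#'
#' @param phantom A `phantom_model`.
#' @param jitter_sigma_mm Per-axis Gaussian vertex jitter (mm).
#' @param resolution_factor Re-mesh the parametric surface at this fraction
#'   of the true resolution (1 = same triangulation).
#' @param seed Seed for the jitter.
#' @return A `surface_mesh` in the CT frame.
#' @export
ct_surface_model <- function(phantom, jitter_sigma_mm = 0.1,
                             resolution_factor = 1, seed = 0L) {
  mesh <- if (resolution_factor == 1) phantom$face else {
    p <- phantom$params
    p$rings <- max(4L, as.integer(round(p$rings * resolution_factor)))
    p$slices <- max(8L, as.integer(round(p$slices * resolution_factor)))
    make_phantom(p, seed = phantom$seed,
                 ct_from_board = phantom$ct_from_board,
                 world_from_ct = phantom$world_from_ct)$face
  }
  if (jitter_sigma_mm > 0) {
    v <- with_seed(seed,
                   mesh$vertices + matrix(rnorm(length(mesh$vertices), 0,
                                                jitter_sigma_mm),
                                          ncol = 3))
    mesh <- surface_mesh(v, mesh$faces)
  }
  mesh
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits exactly the inputs the pipeline and CLI consume: face mesh (PLY and
#' STL), targets and fiducials (CSV), board layout (YAML), ground-truth
#' transforms (JSON).
#'
#' @param phantom A `phantom_model`.
#' @param board A `marker_board` (the tracked reference board).
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom_fixtures <- function(phantom, board, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ply(phantom$face, file.path(dir, "face.ply"))
  write_stl(phantom$face, file.path(dir, "face.stl"), name = "face")
  write_landmarks_csv(
    data.frame(name = sprintf("target_%02d", seq_len(nrow(phantom$targets))),
               x_mm = phantom$targets[, 1], y_mm = phantom$targets[, 2],
               z_mm = phantom$targets[, 3]),
    file.path(dir, "targets.csv"))
  write_landmarks_csv(
    data.frame(name = sprintf("fiducial_%d", phantom$fiducials$id),
               x_mm = phantom$fiducials$x_mm, y_mm = phantom$fiducials$y_mm,
               z_mm = phantom$fiducials$z_mm),
    file.path(dir, "fiducials.csv"))
  write_board_yaml(board, file.path(dir, "board.yaml"))
  write_transform_json(phantom$ct_from_board, file.path(dir, "ct_from_board.json"))
  write_transform_json(phantom$world_from_ct, file.path(dir, "world_from_ct.json"))
  invisible(dir)
}
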