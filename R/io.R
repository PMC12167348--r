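# Plain-text geometry IO: ascii PLY, ascii STL, landmark CSV.

#' Read and write surface meshes and point clouds as ascii PLY
#'
#' @param x A `surface_mesh` or `point_cloud`.
#' @param path File path.
#' @export
write_ply <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "surface_mesh")) {
    v <- x$vertices; f <- x$faces
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (inherits(x, "point_cloud")) {
    v <- x$points
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z")
    if (!is.null(x$normals))
      hdr <- c(hdr, "property double nx", "property double ny",
               "property double nz")
    writeLines(c(hdr, "end_header"), con)
    if (is.null(x$normals)) {
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    } else {
      n <- x$normals
      writeLines(sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                         v[, 1], v[, 2], v[, 3], n[, 1], n[, 2], n[, 3]), con)
    }
  } else stop_endonav("write_ply expects a surface_mesh or point_cloud",
                      "endonav_io_error")
  invisible(path)
}

#' @rdname write_ply
#' @return `read_ply`: a `surface_mesh` (if faces present) or `point_cloud`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop_endonav("not a PLY file", "endonav_io_error")
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  has_normals <- any(grepl("property double nx", hdr))
  body <- lines[(end + 1):length(lines)]
  vparts <- do.call(rbind, strsplit(trimws(body[seq_len(nv)]), "\\s+"))
  v <- matrix(as.numeric(vparts[, 1:3]), nv, 3)
  normals <- if (has_normals) matrix(as.numeric(vparts[, 4:6]), nv, 3) else NULL
  if (nf > 0L) {
    fparts <- do.call(rbind, strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"))
    f <- matrix(as.integer(fparts[, 2:4]) + 1L, nf, 3)
    surface_mesh(v, f)
  } else point_cloud(v, normals)
}

#' Read and write surface meshes as ascii STL
#' @param mesh A `surface_mesh`.
#' @param path File path.
#' @param name Solid name.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- cross3(b - a, c3 - a)
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
                 sprintf("      vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
                 sprintf("      vertex %.17g %.17g %.17g", c3[1], c3[2], c3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' @rdname write_stl
#' @return `read_stl`: a `surface_mesh` (vertices deduplicated exactly).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                  function(p) as.numeric(p[2:4])))
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Read and write landmark tables as CSV (name, x_mm, y_mm, z_mm)
#' @param landmarks Data frame with columns `name`, `x_mm`, `y_mm`, `z_mm`.
#' @param path File path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(all(c("name", "x_mm", "y_mm", "z_mm") %in% names(landmarks)))
  write.csv(landmarks[, c("name", "x_mm", "y_mm", "z_mm")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @return `read_landmarks_csv`: the landmark data frame.
#' @export
read_landmarks_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("name", "x_mm", "y_mm", "z_mm") %in% names(d)))
  d
}
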