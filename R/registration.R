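#' Point clouds and surface meshes
#'
#' A `point_cloud` is an N x 3 matrix of points (mm) with optional unit
#' normals; a `surface_mesh` is a triangulated surface (vertices V x 3 mm,
#' faces F x 3 1-based vertex indices).
#'
#' @param points N x 3 matrix (mm).
#' @param normals Optional N x 3 matrix of unit normals.
#' @return A `point_cloud` object.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as_points_matrix(points)
  if (!is.null(normals)) {
    normals <- as_points_matrix(normals, "normals")
    if (nrow(normals) != nrow(points))
      stop_endonav("one normal per point required", "endonav_invalid_cloud")
    ln <- sqrt(rowSums(normals^2))
    if (nrow(normals) && max(abs(ln - 1)) > 1e-6)
      stop_endonav("normals must be unit length", "endonav_invalid_cloud")
  }
  structure(list(points = points, normals = normals), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else " with normals"))
  invisible(x)
}

#' @rdname point_cloud
#' @param vertices V x 3 vertex matrix (mm).
#' @param faces F x 3 matrix of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as_points_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    stop_endonav("faces must be an F x 3 index matrix", "endonav_invalid_mesh")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_endonav("face indices out of range", "endonav_invalid_mesh")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Two-ring triangle adjacency in CSR form for closest-point queries.
mesh_two_ring <- function(mesh) {
  nv <- nrow(mesh$vertices)
  F <- mesh$faces
  one_ring <- vector("list", nv)
  for (f in seq_len(nrow(F))) {
    one_ring[[F[f, 1]]] <- c(one_ring[[F[f, 1]]], f)
    one_ring[[F[f, 2]]] <- c(one_ring[[F[f, 2]]], f)
    one_ring[[F[f, 3]]] <- c(one_ring[[F[f, 3]]], f)
  }
  two_ring <- vector("list", nv)
  for (v in seq_len(nv)) {
    tris <- one_ring[[v]]
    if (is.null(tris)) { two_ring[[v]] <- integer(0); next }
    verts <- unique(as.integer(F[tris, ]))
    two_ring[[v]] <- unique(unlist(one_ring[verts]))
  }
  counts <- lengths(two_ring)
  list(start = as.integer(cumsum(c(1L, counts))),
       tri = as.integer(unlist(two_ring)))
}

#' Estimate per-point normals from k nearest neighbours
#'
#' Each normal is the smallest principal axis of the k-NN covariance,
#' flipped to point towards the viewpoint (the sensor origin), which is the
#' orientation a depth camera observes.
#'
#' @param cloud A `point_cloud`.
#' @param k_neighbors Neighbourhood size (>= 3).
#' @param viewpoint Sensor origin (mm), default camera origin.
#' @return The cloud with unit `normals` set.
#' @export
estimate_normals <- function(cloud, k_neighbors = 10L, viewpoint = c(0, 0, 0)) {
  pts <- cloud$points
  if (k_neighbors < 3L) stop_endonav("k_neighbors must be >= 3",
                                     "endonav_invalid_cloud")
  if (nrow(pts) < k_neighbors)
    stop_endonav("too few points for normal estimation", "endonav_invalid_cloud")
  idx <- .knn_cpp(pts, as.integer(k_neighbors), FALSE)
  normals <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    nb <- pts[idx[i, ], , drop = FALSE]
    nb <- sweep(nb, 2, colMeans(nb))
    ev <- eigen(crossprod(nb), symmetric = TRUE)
    n <- ev$vectors[, 3]
    if (sum(n * (viewpoint - pts[i, ])) < 0) n <- -n
    normals[i, ] <- n
  }
  point_cloud(pts, normals)
}

#' Robust ICP configuration
#'
#' Defaults follow the published pipeline: Tukey biweight kernel with scale
#' `k = 0.1` mm and a correspondence distance gate of 1 mm. The scale unit
#' is millimetres; `k_unit` must state it explicitly (only `"mm"` accepted)
#' because the source description prints the scale without a unit. Graduated
#' annealing (see [icp_point_to_plane_robust()]) widens both the gate and
#' the kernel early on so a coarse initial alignment can still converge.
#'
#' @param loss `"tukey"` or `"none"` (plain least squares).
#' @param k_mm Tukey scale (mm); may be `Inf`.
#' @param k_unit Unit declaration for the kernel scale; must be `"mm"`.
#' @param threshold_mm Correspondence distance gate (mm).
#' @param max_iterations Iteration cap.
#' @param tol Relative robust-cost change declaring convergence.
#' @param k_neighbors Neighbourhood size for target normal estimation.
#' @param anneal Enable graduated gate/kernel annealing.
#' @param anneal_factor Geometric decay of the annealing multiplier per
#'   iteration (in (0, 1)).
#' @return An `icp_config` object.
#' @export
icp_config <- function(loss = c("tukey", "none"), k_mm = 0.1, k_unit = "mm",
                       threshold_mm = 1, max_iterations = 50L, tol = 1e-10,
                       k_neighbors = 10L, anneal = TRUE, anneal_factor = 0.6) {
  loss <- match.arg(loss)
  if (!identical(k_unit, "mm"))
    stop_endonav("Tukey scale must be declared in \"mm\"", "endonav_units_error")
  if (k_mm <= 0 || threshold_mm <= 0 || max_iterations < 1L)
    stop_endonav("k_mm > 0, threshold_mm > 0, max_iterations >= 1 required",
                 "endonav_invalid_config")
  structure(list(loss = loss, k_mm = k_mm, threshold_mm = threshold_mm,
                 max_iterations = as.integer(max_iterations), tol = tol,
                 k_neighbors = as.integer(k_neighbors), anneal = anneal,
                 anneal_factor = anneal_factor),
            class = "icp_config")
}

#' Tukey biweight weight function
#'
#' `w(r) = (1 - (r/k)^2)^2` for `|r| <= k`, else 0. Residuals beyond the
#' scale `k` get exactly zero influence, which is what makes the kernel
#' robust to gross outliers.
#'
#' @param r Residuals.
#' @param k Kernel scale (same unit as `r`); `Inf` gives unit weights.
#' @return Weights in `[0, 1]`.
#' @export
tukey_weight <- function(r, k) {
  if (!is.finite(k)) return(rep(1, length(r)))
  w <- (1 - (r / k)^2)^2
  w[abs(r) > k] <- 0
  w
}

# Tukey rho (loss) function; r beyond k saturates at k^2/6.
tukey_rho <- function(r, k) {
  if (!is.finite(k)) return(r^2 / 2)
  out <- rep(k^2 / 6, length(r))
  inl <- abs(r) <= k
  out[inl] <- k^2 / 6 * (1 - (1 - (r[inl] / k)^2)^3)
  out
}

# Correspondences of transformed source points against the target
# (cloud-with-normals or mesh). Returns q (matched points), n (normals), d.
icp_correspond <- function(p, target, adj = NULL) {
  if (inherits(target, "surface_mesh")) {
    res <- .closest_point_mesh_cpp(p, target$vertices, target$faces,
                                   adj$start, adj$tri)
    list(q = res$point, n = res$normal, d = res$distance)
  } else {
    nn <- .nn_search_cpp(p, target$points)
    list(q = target$points[nn$index, , drop = FALSE],
         n = target$normals[nn$index, , drop = FALSE],
         d = nn$distance)
  }
}

#' Robust point-to-plane ICP with a Tukey kernel
#'
#' Iterates nearest-neighbour correspondence, distance gating, Tukey
#' weighting of the point-to-plane residuals `r_i = n_i . (T p_i - q_i)`,
#' and a weighted small-angle linearized solve, until the robust cost
#' stabilizes. The target may be a `point_cloud` with normals (classic
#' cloud-to-cloud ICP) or a `surface_mesh`, in which case correspondences
#' are exact closest points on the triangulated surface with face normals —
#' the variant the registration pipeline uses, since its residuals vanish
#' identically when the cloud lies on the surface.
#'
#' When `config$anneal` is on, the gate and kernel start widened by a
#' multiplier derived from the 90th percentile of the initial correspondence
#' distances and shrink geometrically to their configured values, so a
#' coarse prior (tens of degrees / millimetres) still reaches the basin of
#' the tight final gate. Convergence is only declared at the final scale.
#'
#' @param source A `point_cloud` (N >= 6 points).
#' @param target A `point_cloud` with normals, or a `surface_mesh`.
#' @param config An [icp_config()].
#' @param init Initial `target_from_source` transform.
#' @return A `registration_result` list: `transform` (maps the original
#'   source frame to the target frame), `iterations`, `cost` (robust cost at
#'   the final scale), `initial_cost` (at the same scale), `inlier_count`,
#'   `rms` (mm, inlier point-to-plane RMS), `converged`, `status`.
#' @export
icp_point_to_plane_robust <- function(source, target, config = icp_config(),
                                      init = rt_identity()) {
  if (!inherits(source, "point_cloud"))
    stop_endonav("source must be a point_cloud", "endonav_invalid_cloud")
  if (nrow(source$points) < 6L)
    stop_endonav("source needs >= 6 points", "endonav_invalid_cloud")
  is_mesh <- inherits(target, "surface_mesh")
  if (!is_mesh && (!inherits(target, "point_cloud") || is.null(target$normals)))
    stop_endonav("target must be a surface_mesh or a point_cloud with normals",
                 "endonav_invalid_cloud")
  adj <- if (is_mesh) mesh_two_ring(target) else NULL
  src <- source$points
  T_cur <- check_transform(init)
  k_fin <- if (config$loss == "none") Inf else config$k_mm
  tau_fin <- config$threshold_mm

  final_cost_at <- function(tr) {
    co <- icp_correspond(rt_apply(tr, src), target, adj)
    keep <- co$d <= tau_fin
    if (!any(keep)) return(Inf)
    r <- rowSums(co$n[keep, , drop = FALSE] *
                   (rt_apply(tr, src)[keep, , drop = FALSE] -
                      co$q[keep, , drop = FALSE]))
    sum(tukey_rho(r, k_fin))
  }
  initial_cost <- final_cost_at(T_cur)

  mu <- 1
  prev_cost <- Inf
  converged <- FALSE
  status <- "ok"
  iters <- 0L
  final_iters <- 0L
  best_cost <- Inf
  stall_count <- 0L
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    p <- rt_apply(T_cur, src)
    co <- icp_correspond(p, target, adj)
    if (it == 1L && config$anneal) {
      # start with a gate wide enough to cover the whole initial mismatch;
      # point-to-surface distances understate pose error (tangential sliding
      # is invisible to them), hence the factor of 3
      mu <- max(1, 3 * as.numeric(quantile(co$d, 0.9)) / tau_fin)
    }
    tau <- tau_fin * mu
    # while annealing, the gate itself is the robustifier: the kernel is
    # held at the current gate width so the coarse alignment keeps enough
    # gradient; at mu == 1 the configured scale applies exactly
    k_eff <- if (mu > 1) max(k_fin * mu, tau) else k_fin
    keep <- which(co$d <= tau)
    if (length(keep) == 0L) {
      status <- "no_overlap"
      break
    }
    pk <- p[keep, , drop = FALSE]
    qk <- co$q[keep, , drop = FALSE]
    nk <- co$n[keep, , drop = FALSE]
    r <- rowSums(nk * (pk - qk))
    w <- if (config$loss == "tukey") tukey_weight(r, k_eff) else rep(1, length(r))
    if (sum(w > 0) < 6L) {
      # kernel collapsed: widen to the residual scale for this iteration
      k_eff <- max(k_eff, 3 * median(abs(r)) + 1e-12)
      w <- tukey_weight(r, k_eff)
    }
    cx <- cbind(pk[, 2] * nk[, 3] - pk[, 3] * nk[, 2],
                pk[, 3] * nk[, 1] - pk[, 1] * nk[, 3],
                pk[, 1] * nk[, 2] - pk[, 2] * nk[, 1])
    A <- cbind(cx, nk)
    Aw <- A * w
    lhs <- crossprod(Aw, A)
    rhs <- -crossprod(Aw, r)
    x <- tryCatch(as.numeric(solve(lhs + 1e-12 * diag(6), rhs)),
                  error = function(e) rep(0, 6))
    delta <- rigid_transform(rotvec_to_matrix(x[1:3]), x[4:6])
    T_cur <- rt_compose(delta, T_cur)
    cost <- sum(tukey_rho(r, k_eff))
    step <- max(sqrt(sum(x[1:3]^2)), sqrt(sum(x[4:6]^2)))
    if (mu <= 1 + 1e-12) {
      # converged when the update is numerically zero or the best cost seen
      # at the final scale has not improved by tol for 5 iterations
      # (correspondence churn makes the raw cost bounce around its plateau)
      final_iters <- final_iters + 1L
      if (cost < best_cost * (1 - config$tol) || final_iters == 1L) {
        best_cost <- cost
        stall_count <- 0L
      } else {
        stall_count <- stall_count + 1L
      }
      if (step < 1e-10 || stall_count >= 5L) {
        converged <- TRUE
        break
      }
      prev_cost <- cost
    } else {
      # graduated scheme: iterate at the current scale until progress
      # stalls, then tighten the gate/kernel one notch
      stalled <- abs(prev_cost - cost) <= 1e-2 * (abs(prev_cost) + 1e-12) ||
        step < 1e-7
      if (stalled) {
        mu <- max(1, mu * config$anneal_factor)
        prev_cost <- Inf  # scales changed; cost not comparable yet
      } else {
        prev_cost <- cost
      }
    }
  }

  # final-scale summary
  p <- rt_apply(T_cur, src)
  co <- icp_correspond(p, target, adj)
  keep <- which(co$d <= tau_fin)
  if (length(keep)) {
    r <- rowSums(co$n[keep, , drop = FALSE] *
                   (p[keep, , drop = FALSE] - co$q[keep, , drop = FALSE]))
    w <- if (config$loss == "tukey") tukey_weight(r, k_fin) else rep(1, length(r))
    inlier <- sum(w > 0)
    rms <- if (inlier) sqrt(mean(r[w > 0]^2)) else NA_real_
    cost <- sum(tukey_rho(r, k_fin))
  } else {
    inlier <- 0L
    rms <- NA_real_
    cost <- Inf
    if (status == "ok") status <- "no_overlap"
  }
  structure(list(transform = T_cur, iterations = iters, cost = cost,
                 initial_cost = initial_cost, inlier_count = inlier,
                 rms = rms, converged = converged, status = status),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result> %s after %d iterations, cost %.3g,",
                     " %d inliers, RMS %.4g mm\n"),
              if (x$converged) "converged" else "stopped", x$iterations,
              x$cost, x$inlier_count, x$rms))
  invisible(x)
}

#' Move the CT surface into the camera frame using prior knowledge
#'
#' The automatic registration starts from prior knowledge of the depth
#' camera's pose relative to the face: the CT surface is oriented the same
#' way as the reconstruction before ICP refines the alignment. The prior is
#' recorded on the result so the final registration can be reported in the
#' original CT frame.
#'
#' @param ct_surface A `surface_mesh` in the CT frame.
#' @param prior `rigid_transform` `camera_from_ct`.
#' @return A `point_cloud` of the transformed CT vertices with attribute
#'   `"prior"`.
#' @export
initial_align_from_prior <- function(ct_surface, prior) {
  check_transform(prior)
  cl <- point_cloud(rt_apply(prior, ct_surface$vertices))
  attr(cl, "prior") <- prior
  cl
}

#' Register a depth-camera reconstruction to the CT surface
#'
#' The pipeline registration: the back-projected depth cloud (camera frame)
#' is aligned onto the CT surface mesh by robust point-to-plane ICP, started
#' from the supplied prior. Internally the cloud is moved onto the mesh
#' (exact closest-point correspondences); the returned transform is the
#' `camera_from_ct` pose the navigation chain needs.
#'
#' @param cloud A `point_cloud` in the depth-camera frame.
#' @param ct_surface A `surface_mesh` in the CT frame.
#' @param prior Prior `camera_from_ct` transform.
#' @param config An [icp_config()].
#' @param max_points Subsample the cloud to at most this many points
#'   (seeded, deterministic) before ICP.
#' @param seed Seed for the subsampling.
#' @return List with `camera_from_ct` and the full `registration_result`
#'   (whose `transform` is `ct_from_camera`).
#' @export
register_depth_to_ct <- function(cloud, ct_surface, prior,
                                 config = icp_config(), max_points = 4000L,
                                 seed = 0L) {
  pts <- cloud$points
  if (nrow(pts) > max_points) {
    keep <- with_seed(seed, sample.int(nrow(pts), max_points))
    pts <- pts[keep, , drop = FALSE]
  }
  res <- icp_point_to_plane_robust(point_cloud(pts), ct_surface, config,
                                   init = rt_invert(prior))
  list(camera_from_ct = rt_invert(res$transform), result = res)
}

#' Closed-form rigid Procrustes (Arun) registration
#'
#' SVD solution minimizing `sum ||T s_i - t_i||^2` over rigid transforms,
#' with the reflection guarded by a sign correction on the smallest singular
#' vector. FRE is the RMS residual after alignment.
#'
#' @param source_points,target_points K x 3 matrices (mm), corresponding by
#'   row, K >= 3, non-collinear.
#' @return List with `transform` (`target_from_source`) and `fre` (mm).
#' @export
procrustes_register <- function(source_points, target_points) {
  s <- as_points_matrix(source_points, "source_points")
  t <- as_points_matrix(target_points, "target_points")
  if (nrow(s) != nrow(t) || nrow(s) < 3L)
    stop_endonav("need >= 3 corresponding point pairs", "endonav_degenerate")
  cs <- colMeans(s); ct <- colMeans(t)
  sc <- sweep(s, 2, cs); tc <- sweep(t, 2, ct)
  H <- crossprod(sc, tc)
  dvals <- svd(sweep(s, 2, cs), nu = 0, nv = 0)$d
  if (dvals[2] <= 1e-8 * max(dvals[1], 1e-12))
    stop_endonav("degenerate geometry: points are collinear", "endonav_degenerate")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cs)
  transform <- rigid_transform(R, tr)
  resid <- rt_apply(transform, s) - t
  list(transform = transform, fre = sqrt(mean(rowSums(resid^2))))
}

#' Fold the surface registration into the board reference
#'
#' At the registration frame the depth camera simultaneously knows its pose
#' relative to the CT (from surface registration) and relative to the
#' fiducial board. Their combination `board_from_ct` is the persistent
#' registration: from then on the board is the sole patient reference.
#'
#' @param camera_from_ct Registration result (`camera_from_ct`).
#' @param camera_from_board_at_registration Board pose at the same frame.
#' @return `rigid_transform` `board_from_ct`.
#' @export
compose_ct_to_reference <- function(camera_from_ct,
                                    camera_from_board_at_registration) {
  rt_compose(rt_invert(camera_from_board_at_registration), camera_from_ct)
}
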