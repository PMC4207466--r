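# Parametric model of the dentate gyrus granule-cell and molecular layers.
#
# The construction follows the recipe of carving a "C"-shaped piece out of a
# torus with an elliptical cross-section, deflecting it in z along the
# septotemporal axis, and making the septal and temporal ends unequal.
# Coordinates:
#   u : septotemporal angle (radians around the torus center circle)
#   v : transverse angle around the cross-section ellipse (the "C"-shape)
#   L : layer offset indexing the boundary shells
#       (-1.95 inner GCL, 0 outer GCL, 1 IML, 2 MML, 3 OML)
# Layer shells are parallel-offset curves of the base cross-section ellipse,
# offset along the local ellipse normal by a distance proportional to L
# (GCL and ML have separately calibrated thicknesses).  Because the offset
# direction lies in the cross-section plane, the whole construction is
# invertible in cylindrical coordinates, which gives an exact point
# classifier (see dg_coords).

#' Parameters of the dentate gyrus surface model
#'
#' Returns the parameter set defining the layered parametric volume.  The
#' angular ranges are fixed anatomical constants; the metric coefficients
#' (radii, thicknesses, deflection, end-taper) default to values calibrated
#' so that the model reproduces the measured granule cell layer volume
#' (3.78 mm^3), molecular layer volume (9.02 mm^3) and mean molecular layer
#' width (247 um).  See `scripts/calibrate_geometry.R` in the source
#' repository for the calibration procedure.
#'
#' @param R center-circle radius of the torus (um)
#' @param A0,B0 cross-section ellipse semi-axes at mid septotemporal
#'   extent: radial (in the torus plane) and vertical (um)
#' @param eps_a,eps_b relative end-taper of `A0`/`B0` (`A(u) = A0 (1 +
#'   eps_a cos u)`); negative values make the septal end (u = 0) smaller
#'   and sharper
#' @param Dz amplitude of the z deflection `z0(u) = Dz sin(u)` (um)
#' @param w_gcl granule cell layer thickness (um)
#' @param w_ml0 molecular layer base thickness (um)
#' @param eps_w relative septotemporal modulation of the ML thickness
#' @param soma_diameter granule cell soma diameter (um)
#' @return An object of class `dg_surface_params` (a named list).
#' @export
dg_surface_params <- function(R = 3044.31, A0 = 716.31, B0 = 447.69,
                              eps_a = -0.18, eps_b = -0.05,
                              Dz = 1253.54,
                              w_gcl = 164.818, w_ml0 = 255.852, eps_w = 0.185,
                              soma_diameter = 12.54) {
  p <- list(
    R = R, A0 = A0, B0 = B0, eps_a = eps_a, eps_b = eps_b, Dz = Dz,
    w_gcl = w_gcl, w_ml0 = w_ml0, eps_w = eps_w,
    soma_diameter = soma_diameter,
    v_range = c(-0.23 * pi, 1.425 * pi),
    u_range_gcl = c(0.01 * pi, 0.98 * pi),
    u_range_ml = c(-0.016 * pi, 1.01 * pi),
    L_inner_gcl = -1.95, L_oml = 3)
  class(p) <- "dg_surface_params"
  p
}

# cross-section ellipse semi-axes at septotemporal angle u
.dg_axes <- function(p, u) {
  list(A = p$A0 * (1 + p$eps_a * cos(u)),
       B = p$B0 * (1 + p$eps_b * cos(u)))
}

# local ML thickness at u
.dg_wml <- function(p, u) p$w_ml0 * (1 + p$eps_w * cos(u))

# signed offset distance (um) of layer shell L from the base (outer GCL) curve
.dg_offset <- function(p, u, L) {
  ifelse(L < 0, p$w_gcl * L / abs(p$L_inner_gcl), .dg_wml(p, u) * L / p$L_oml)
}

#' Evaluate a point on a layer boundary surface
#'
#' @param volume a `dg_volume` (or `dg_surface_params`) object
#' @param u,v septotemporal and transverse angles (radians); vectors are
#'   recycled to common length
#' @param L layer offset; one of the values in \{-1.95, 0, 1, 2, 3\} or any
#'   intermediate value in that range
#' @param check if `TRUE` (default), error on out-of-range `u`, `v`, `L`
#' @return numeric matrix with columns x, y, z (um)
#' @export
surface_point <- function(volume, u, v, L = 0, check = TRUE) {
  p <- if (inherits(volume, "dg_volume")) volume$params else volume
  n <- max(length(u), length(v), length(L))
  u <- rep_len(u, n); v <- rep_len(v, n); L <- rep_len(L, n)
  if (check) {
    u_lo <- ifelse(L > 0, p$u_range_ml[1], p$u_range_gcl[1])
    u_hi <- ifelse(L > 0, p$u_range_ml[2], p$u_range_gcl[2])
    if (any(u < u_lo - 1e-9 | u > u_hi + 1e-9))
      stop("u outside the valid septotemporal range for this layer")
    if (any(v < p$v_range[1] - 1e-9 | v > p$v_range[2] + 1e-9))
      stop("v outside the transverse range")
    if (any(L < p$L_inner_gcl - 1e-9 | L > p$L_oml + 1e-9))
      stop("L outside the layer offset range")
  }
  ax <- .dg_axes(p, u)
  d <- .dg_offset(p, u, L)
  nx <- ax$B * cos(v); nz <- ax$A * sin(v)
  nn <- sqrt(nx^2 + nz^2)
  xi <- ax$A * cos(v) + d * nx / nn
  ze <- ax$B * sin(v) + d * nz / nn
  cbind(x = (p$R + xi) * cos(u),
        y = (p$R + xi) * sin(u),
        z = p$Dz * sin(u) + ze)
}

#' Build the dentate gyrus volume model
#'
#' Constructs the layered volume object used by all downstream stages:
#' parameter set, bounding box, and (lazily built) boundary point clouds.
#'
#' @param params a `dg_surface_params` object
#' @return An object of class `dg_volume`.
#' @export
build_dg_volume <- function(params = dg_surface_params()) {
  p <- params
  # bounding box from a dense sweep of the two extreme shells
  uu <- seq(p$u_range_ml[1], p$u_range_ml[2], length.out = 160)
  vv <- seq(p$v_range[1], p$v_range[2], length.out = 160)
  g <- expand.grid(u = uu, v = vv)
  pts <- rbind(surface_point(p, g$u, g$v, p$L_oml, check = FALSE),
               surface_point(p, g$u, g$v, p$L_inner_gcl, check = FALSE))
  pad <- 10
  bbox <- rbind(lo = apply(pts, 2, min) - pad, hi = apply(pts, 2, max) + pad)
  vol <- list(params = p, bbox = bbox, cache = new.env(parent = emptyenv()))
  class(vol) <- "dg_volume"
  vol
}

#' @export
print.dg_volume <- function(x, ...) {
  p <- x$params
  cat("Dentate gyrus parametric volume\n")
  cat(sprintf("  torus radius %g um, cross-section %g x %g um\n", p$R, p$A0, p$B0))
  cat(sprintf("  GCL thickness %g um, ML thickness %g um (x 1%+.2f cos u)\n",
              p$w_gcl, p$w_ml0, p$eps_w))
  bb <- x$bbox
  cat(sprintf("  bounding box %.0f x %.0f x %.0f um\n",
              bb[2,1]-bb[1,1], bb[2,2]-bb[1,2], bb[2,3]-bb[1,3]))
  invisible(x)
}

# Vectorized Newton projection of cross-section points (xi, ze) onto the
# ellipse with semi-axes (A, B): returns foot parameter t and signed distance
# (positive outside the ellipse, i.e. toward the molecular layer).
.ellipse_project <- function(xi, ze, A, B, iter = 40) {
  t <- atan2(ze * A, xi * B)
  for (i in seq_len(iter)) {
    ct <- cos(t); st <- sin(t)
    ex <- A * ct - xi; ey <- B * st - ze
    f  <- -A * st * ex + B * ct * ey
    fp <- -A * ct * ex + A^2 * st^2 - B * st * ey + B^2 * ct^2
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 0.5), -0.5)  # damped for robustness far away
    t <- t - step
  }
  ct <- cos(t); st <- sin(t)
  dist <- sqrt((A * ct - xi)^2 + (B * st - ze)^2)
  outside <- (xi / A)^2 + (ze / B)^2 > 1
  list(t = t, d = ifelse(outside, dist, -dist))
}

#' Intrinsic coordinates of arbitrary 3D points
#'
#' Maps points to the intrinsic (u, v, d) coordinates of the layered model:
#' septotemporal angle `u`, transverse foot angle `v` on the base ellipse,
#' and signed offset distance `d` (um) from the outer GCL shell (negative
#' toward the hilus, positive toward the OML).  Used by the classifier, the
#' soma packer and the laminar morphometrics.
#'
#' @param volume a `dg_volume`
#' @param pts numeric matrix with columns x, y, z (um)
#' @return data.frame with columns u, v, d, w_ml (local ML thickness).
#' @export
dg_coords <- function(volume, pts) {
  p <- volume$params
  pts <- as_xyz(pts)
  u <- atan2(pts[, 2], pts[, 1])
  u <- ifelse(u < -0.5 * pi, u + 2 * pi, u)
  xi <- sqrt(pts[, 1]^2 + pts[, 2]^2) - p$R
  ze <- pts[, 3] - p$Dz * sin(u)
  ax <- .dg_axes(p, u)
  pr <- .ellipse_project(xi, ze, ax$A, ax$B)
  v <- ifelse(pr$t <= -0.575 * pi, pr$t + 2 * pi, pr$t)
  data.frame(u = u, v = v, d = pr$d, w_ml = .dg_wml(p, u))
}

#' Classify points into dentate gyrus layers
#'
#' Total function: any finite 3D point maps to one of
#' GCL, IML, MML, OML or OUTSIDE.  Layer bands are half-open toward the
#' outside, so a point exactly on a shared boundary belongs to the outer
#' of the two layers.
#'
#' @param volume a `dg_volume` or toy volume object
#' @param pts numeric matrix with columns x, y, z (um)
#' @return factor of layer labels with levels [DG_LAYERS].
#' @export
classify_points <- function(volume, pts) UseMethod("classify_points")

#' @export
classify_points.dg_volume <- function(volume, pts) {
  p <- volume$params
  pts <- as_xyz(pts)
  lab <- rep("OUTSIDE", nrow(pts))
  ok <- is.finite(pts[, 1]) & is.finite(pts[, 2]) & is.finite(pts[, 3])
  # cheap pre-filter: anything far from the torus shell is outside
  r_max <- max(abs(.dg_axes(p, c(0, pi))$A)) + p$w_ml0 * (1 + p$eps_w) + 50
  rxy <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  near <- ok & abs(rxy - p$R) < r_max & abs(pts[, 3]) < p$Dz + p$B0 * 1.3 + r_max
  if (any(near)) {
    co <- dg_coords(volume, pts[near, , drop = FALSE])
    v_ok <- co$v >= p$v_range[1] & co$v <= p$v_range[2]
    u_gcl <- co$u >= p$u_range_gcl[1] & co$u <= p$u_range_gcl[2]
    u_ml <- co$u >= p$u_range_ml[1] & co$u <= p$u_range_ml[2]
    l <- rep("OUTSIDE", nrow(co))
    w3 <- co$w_ml / 3
    l[v_ok & u_gcl & co$d >= -p$w_gcl & co$d < 0] <- "GCL"
    l[v_ok & u_ml & co$d >= 0 & co$d < w3] <- "IML"
    l[v_ok & u_ml & co$d >= w3 & co$d < 2 * w3] <- "MML"
    l[v_ok & u_ml & co$d >= 2 * w3 & co$d <= co$w_ml] <- "OML"
    lab[near] <- l
  }
  factor(lab, levels = DG_LAYERS)
}

#' Monte-Carlo layer volume estimate
#'
#' Rejection sampling in the bounding box.  Reported in mm^3 with the
#' binomial standard error of the estimate.
#'
#' @param volume a volume object
#' @param layers character vector of layer labels to include; `"ML"` is
#'   shorthand for `c("IML", "MML", "OML")`
#' @param n_samples number of uniform samples (>= 1e5)
#' @param seed integer seed for reproducibility
#' @param chunk samples per vectorized batch
#' @return list with elements `volume_mm3`, `se_mm3`, `n`, `frac`.
#' @export
estimate_volume <- function(volume, layers = "GCL", n_samples = 1e6,
                            seed = 1, chunk = 2e6) {
  if (n_samples < 1e5) stop("n_samples must be at least 1e5")
  if (identical(layers, "ML")) layers <- c("IML", "MML", "OML")
  bb <- vol_bbox(volume)
  ext <- bb[2, ] - bb[1, ]
  if (any(ext <= 0)) stop("degenerate bounding box")
  vbox <- prod(ext)
  set.seed(seed)
  hits <- 0; done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    pts <- cbind(runif(m, bb[1, 1], bb[2, 1]),
                 runif(m, bb[1, 2], bb[2, 2]),
                 runif(m, bb[1, 3], bb[2, 3]))
    hits <- hits + sum(classify_points(volume, pts) %in% layers)
    done <- done + m
  }
  frac <- hits / n_samples
  list(volume_mm3 = frac * vbox * 1e-9,
       se_mm3 = sqrt(frac * (1 - frac) / n_samples) * vbox * 1e-9,
       n = n_samples, frac = frac)
}

#' Sample points uniformly on a layer boundary surface
#'
#' Area-weighted rejection sampling in (u, v) using the numerical surface
#' Jacobian, so the cloud is uniform per unit area.  Clouds for the outer
#' GCL (L = 0) and OML (L = 3) shells are cached on the volume object.
#'
#' @param volume a `dg_volume`
#' @param L layer offset of the shell
#' @param n number of points
#' @param seed integer seed
#' @return matrix (n x 3) of surface points (um).
#' @export
boundary_cloud <- function(volume, L = 3, n = 2e6, seed = 1)
  UseMethod("boundary_cloud")

#' @export
boundary_cloud.dg_volume <- function(volume, L = 3, n = 2e6, seed = 1) {
  p <- volume$params
  key <- sprintf("cloud_L%g_n%g_s%d", L, n, as.integer(seed))
  if (!is.null(volume$cache[[key]])) return(volume$cache[[key]])
  ur <- if (L > 0) p$u_range_ml else p$u_range_gcl
  vr <- p$v_range
  jac <- function(u, v) {
    h <- 1e-4
    pu <- (surface_point(p, u + h, v, L, check = FALSE) -
           surface_point(p, u - h, v, L, check = FALSE)) / (2 * h)
    pv <- (surface_point(p, u, v + h, L, check = FALSE) -
           surface_point(p, u, v - h, L, check = FALSE)) / (2 * h)
    cr <- cbind(pu[, 2] * pv[, 3] - pu[, 3] * pv[, 2],
                pu[, 3] * pv[, 1] - pu[, 1] * pv[, 3],
                pu[, 1] * pv[, 2] - pu[, 2] * pv[, 1])
    sqrt(rowSums(cr^2))
  }
  set.seed(seed)
  gu <- seq(ur[1], ur[2], length.out = 40)
  gv <- seq(vr[1], vr[2], length.out = 40)
  gg <- expand.grid(u = gu, v = gv)
  jmax <- max(jac(gg$u, gg$v)) * 1.1
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 1.6) + 1000
    u <- runif(m, ur[1], ur[2]); v <- runif(m, vr[1], vr[2])
    keep <- runif(m) * jmax < jac(u, v)
    out <- rbind(out, surface_point(p, u[keep], v[keep], L, check = FALSE))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  volume$cache[[key]] <- out
  out
}

#' Molecular layer width
#'
#' Distributes points on the outer GCL and OML boundary shells, samples
#' `n_query` outer-GCL points, and reports the mean and standard deviation
#' of their nearest-neighbor distances to the OML cloud.
#'
#' @param volume a `dg_volume`
#' @param n_boundary points per boundary cloud
#' @param n_query number of sampled outer GCL points
#' @param seed integer seed
#' @return list with `mean_um`, `sd_um`, `distances`.
#' @export
ml_width <- function(volume, n_boundary = 2e6, n_query = 1e4, seed = 1) {
  gcl <- boundary_cloud(volume, L = 0, n = n_boundary, seed = seed)
  oml <- boundary_cloud(volume, L = 3, n = n_boundary, seed = seed + 1)
  if (nrow(gcl) == 0 || nrow(oml) == 0) stop("empty boundary cloud")
  set.seed(seed + 2)
  q <- gcl[sample.int(nrow(gcl), min(n_query, nrow(gcl))), , drop = FALSE]
  d <- .nn_grid(q, oml, cell_size = 100)$distance
  list(mean_um = mean(d), sd_um = sd(d), distances = d)
}

#' Transverse slice predicate
#'
#' Returns a predicate selecting points inside a planar slab orthogonal to
#' the local septotemporal direction at angle `u0` (the plane contains the
#' torus axis), as used for slice renderings and slice-restricted analyses.
#'
#' @param volume a `dg_volume`
#' @param u0 septotemporal angle of the slice center
#' @param thickness slab thickness (um)
#' @return function taking an (n x 3) point matrix, returning a logical vector.
#' @export
transverse_slice <- function(volume, u0, thickness) {
  if (thickness < 0) stop("thickness must be non-negative")
  force(u0); force(thickness)
  function(pts) {
    pts <- as_xyz(pts)
    dplane <- -pts[, 1] * sin(u0) + pts[, 2] * cos(u0)
    ahead <- pts[, 1] * cos(u0) + pts[, 2] * sin(u0) > 0
    abs(dplane) < thickness / 2 & ahead
  }
}

#' Transverse curve curvature at the crest
#'
#' Curvature of the outer GCL transverse curve at the crest of the "C"
#' (the midpoint of the `v` range) for a given septotemporal position.
#' Septal cross-sections are sharper ("V"-shaped) than temporal ones
#' ("U"-shaped), so the septal crest curvature exceeds the temporal one.
#'
#' @param volume a `dg_volume`
#' @param u septotemporal angle
#' @param v transverse angle at which to evaluate (default: crest)
#' @return curvature (1/um) of the transverse curve at `v`.
#' @export
transverse_curvature <- function(volume, u, v = mean(volume$params$v_range)) {
  ax <- .dg_axes(volume$params, u)
  # curvature of the ellipse A cos v, B sin v
  ax$A * ax$B / (ax$A^2 * sin(v)^2 + ax$B^2 * cos(v)^2)^1.5
}

#' Triangulated boundary mesh
#'
#' Triangulates a layer shell on a regular (u, v) grid; used for surface
#' maps and for OFF export.
#'
#' @param volume a `dg_volume`
#' @param L layer offset of the shell
#' @param n_faces approximate number of triangular faces
#' @return list with `vertices` (m x 3), `faces` (k x 3, 1-based indices),
#'   `centroids` (k x 3), and the (u, v) of each vertex.
#' @export
boundary_mesh <- function(volume, L = 0, n_faces = 5000) {
  p <- volume$params
  ur <- if (L > 0) p$u_range_ml else p$u_range_gcl
  vr <- p$v_range
  # grid aspect from physical extents: u arc ~ pi*R, v arc ~ ellipse arc
  aspect <- (pi * p$R) / (1.655 * pi * (p$A0 + p$B0) / 2)
  nv <- max(4, round(sqrt(n_faces / (2 * aspect))))
  nu <- max(4, round(n_faces / (2 * nv)))
  gu <- seq(ur[1], ur[2], length.out = nu + 1)
  gv <- seq(vr[1], vr[2], length.out = nv + 1)
  gg <- expand.grid(u = gu, v = gv)
  verts <- surface_point(p, gg$u, gg$v, L, check = FALSE)
  vid <- function(i, j) (j - 1) * (nu + 1) + i
  f <- vector("list", nu * nv)
  idx <- 1
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    f[[idx]] <- rbind(c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
                      c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)))
    idx <- idx + 1
  }
  faces <- do.call(rbind, f)
  cent <- (verts[faces[, 1], ] + verts[faces[, 2], ] + verts[faces[, 3], ]) / 3
  list(vertices = verts, faces = faces, centroids = cent,
       uv = as.matrix(gg))
}

#' Export a boundary mesh in OFF format
#'
#' @param mesh result of [boundary_mesh()]
#' @param path output file path
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  write.table(format(mesh$vertices, trim = TRUE), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(cbind(3, mesh$faces - 1), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bounding box of a volume object
#' @param volume a volume object
#' @return 2 x 3 matrix (rows lo, hi)
#' @export
vol_bbox <- function(volume) UseMethod("vol_bbox")

#' @export
vol_bbox.dg_volume <- function(volume) volume$bbox

# coerce inputs to an n x 3 numeric matrix
as_xyz <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y", "z")])
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  storage.mode(pts) <- "double"
  pts
}
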