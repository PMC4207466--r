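# Target points: candidate locations for dendritic nodes.  Each cell
# selects target points inside an elliptical cone with its apex at the
# soma, oriented toward the nearest point of the OML outer boundary; the
# transverse radius exceeds the longitudinal radius, matching the wider
# transverse dendritic field of granule cells.

#' Orient a cell's elliptical cone
#'
#' The cone axis points from the soma to the nearest of the points
#' distributed on the OML outer boundary; the cone height reaches that
#' boundary.  The transverse semi-axis is aligned with the local
#' transverse (v) tangent of the layered volume and the longitudinal
#' semi-axis with the septotemporal (u) tangent, both projected
#' perpendicular to the axis.
#'
#' @param volume a `dg_volume`
#' @param soma length-3 numeric (um) or one-row `soma_set`
#' @param oml_cloud matrix of points on the OML boundary (see
#'   [boundary_cloud()])
#' @param rt,rl transverse and longitudinal base semi-radii (um);
#'   `rt > rl` is required
#' @param overshoot multiplicative height margin past the OML boundary
#' @param apex_offset distance (um) the cone apex is displaced below the
#'   soma along the axis; a positive offset gives the cone a non-zero
#'   cross-section at the soma, so the dendritic fan can open immediately
#'   above the cell body
#' @return object of class `elliptical_cone`: apex, axis, t_hat, l_hat,
#'   rt, rl, h.
#' @export
orient_cone <- function(volume, soma, oml_cloud, rt, rl, overshoot = 1.02,
                        apex_offset = 0) {
  if (rt <= rl) stop("transverse radius must exceed longitudinal radius")
  apex <- if (is.data.frame(soma)) c(soma$x[1], soma$y[1], soma$z[1])
          else as.numeric(soma[1:3])
  if (classify_points(volume, matrix(apex, 1)) == "OUTSIDE")
    stop("soma lies outside the model volume")
  nn <- .nn_grid(matrix(apex, 1), oml_cloud, cell_size = 100)
  target <- oml_cloud[nn$index[1], ]
  axis <- target - apex
  h <- sqrt(sum(axis^2))
  axis <- axis / h
  co <- dg_coords(volume, matrix(apex, 1))
  p <- volume$params
  eps <- 1e-3
  tu <- (surface_point(p, co$u + eps, co$v, 0, check = FALSE) -
         surface_point(p, co$u - eps, co$v, 0, check = FALSE))[1, ]
  tv <- (surface_point(p, co$u, co$v + eps, 0, check = FALSE) -
         surface_point(p, co$u, co$v - eps, 0, check = FALSE))[1, ]
  t_hat <- tv - sum(tv * axis) * axis
  t_hat <- t_hat / sqrt(sum(t_hat^2))
  l_hat <- c(axis[2] * t_hat[3] - axis[3] * t_hat[2],
             axis[3] * t_hat[1] - axis[1] * t_hat[3],
             axis[1] * t_hat[2] - axis[2] * t_hat[1])
  if (sum(l_hat * tu) < 0) l_hat <- -l_hat
  structure(list(apex = apex - apex_offset * axis, soma = apex,
                 axis = axis, t_hat = t_hat, l_hat = l_hat,
                 rt = rt, rl = rl, h = h * overshoot + apex_offset),
            class = "elliptical_cone")
}

# cone-frame coordinates of points: columns t (transverse), l
# (longitudinal), z (along axis)
cone_frame <- function(cone, pts) {
  pts <- as_xyz(pts)
  w <- sweep(pts, 2, cone$apex)
  out <- cbind(w %*% cone$t_hat, w %*% cone$l_hat, w %*% cone$axis)
  colnames(out) <- c("t", "l", "z")
  out
}

#' Select points inside an elliptical cone
#'
#' A point at height z along the axis is inside if
#' `(t/rt)^2 + (l/rl)^2 <= (z/h)^2` with `z` in `[0, h]`.
#'
#' @param cone an `elliptical_cone`
#' @param pts point matrix or `target_cloud` data.frame
#' @return logical vector.
#' @export
cone_select <- function(cone, pts) {
  if (cone$rt <= 0 || cone$rl <= 0 || cone$h <= 0)
    stop("degenerate cone radii")
  f <- cone_frame(cone, pts)
  f[, "z"] >= 0 & f[, "z"] <= cone$h &
    (f[, "t"] / cone$rt)^2 + (f[, "l"] / cone$rl)^2 <=
      (f[, "z"] / cone$h)^2 + 1e-12
}

# samples inside the cone volume; z_exp = 3 is uniform in volume, larger
# values bias the axial position toward the cone base (distal)
sample_in_cone <- function(cone, n, z_exp = 3) {
  z <- cone$h * runif(n)^(1 / z_exp)
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  t <- cone$rt * (z / cone$h) * r * cos(th)
  l <- cone$rl * (z / cone$h) * r * sin(th)
  pts <- matrix(cone$apex, n, 3, byrow = TRUE) +
    outer(z, cone$axis) + outer(as.numeric(t), cone$t_hat) +
    outer(as.numeric(l), cone$l_hat)
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Draw a per-cell laminar target-point quota
#'
#' The per-layer counts are Poisson draws around subgroup mean quotas
#' scaled by a common lognormal per-cell size factor, so that per-cell
#' totals vary realistically while population means stay calibrated.
#' Uses the current RNG state.
#'
#' @param subgroup subgroup label
#' @param tab subgroup parameter table ([default_subgroup_params()])
#' @return named integer vector (GCL, IML, MML, OML).
#' @export
draw_quota <- function(subgroup, tab = default_subgroup_params()) {
  row <- tab[subgroup, ]
  if (is.na(row$bf)) stop("unknown subgroup: ", subgroup)
  cv <- row$size_cv
  s <- exp(rnorm(1, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))))
  f <- c(GCL = row$f_gcl, IML = row$f_iml, MML = row$f_mml, OML = row$f_oml)
  q <- rpois(4, row$n_nodes * s * f / sum(f))
  names(q) <- names(f)
  q
}

#' Sample a shared target-point cloud
#'
#' Distributes points uniformly in the GCL and molecular layer (optionally
#' restricted by a slice predicate), tagging each with its layer, as a
#' shared pool from which cells may mark points unavailable.
#'
#' @param volume a volume object
#' @param n number of accepted points
#' @param layers layers to populate
#' @param slice optional predicate from [transverse_slice()]
#' @param seed integer seed
#' @return `target_cloud` data.frame: x, y, z, layer, available.
#' @export
make_target_cloud <- function(volume, n, layers = c("GCL", "IML", "MML", "OML"),
                              slice = NULL, seed = 1) {
  bb <- vol_bbox(volume)
  set.seed(seed)
  out <- vector("list", 0)
  got <- 0
  while (got < n) {
    m <- max(5000, ceiling((n - got) * 8))
    pts <- cbind(x = runif(m, bb[1, 1], bb[2, 1]),
                 y = runif(m, bb[1, 2], bb[2, 2]),
                 z = runif(m, bb[1, 3], bb[2, 3]))
    lab <- classify_points(volume, pts)
    keep <- lab %in% layers
    if (!is.null(slice)) keep <- keep & slice(pts)
    if (any(keep)) {
      out[[length(out) + 1]] <-
        data.frame(pts[keep, , drop = FALSE], layer = lab[keep])
      got <- got + sum(keep)
    }
  }
  cloud <- do.call(rbind, out)[seq_len(n), ]
  rownames(cloud) <- NULL
  cloud$available <- TRUE
  class(cloud) <- c("target_cloud", "data.frame")
  cloud
}

# Per-cell target selection. In the default independent mode, candidate
# points are sampled inside the cone and thinned to the laminar quota.
# In shared mode, points are taken from the supplied global cloud and
# marked unavailable.
select_targets <- function(volume, cone, quota, cloud = NULL,
                           oversample = 8, z_exp = 3, within_bias = 0) {
  if (is.null(cloud)) {
    pool <- sample_in_cone(cone, max(200, oversample * sum(quota)), z_exp)
    lab <- as.character(classify_points(volume, pool))
  } else {
    inside <- cone_select(cone, cloud) & cloud$available
    pool <- as_xyz(cloud[inside, c("x", "y", "z")])
    lab <- as.character(cloud$layer[inside])
    attr(pool, "cloud_rows") <- which(inside)
  }
  zax <- cone_frame(cone, pool)[, "z"]
  picks <- integer(0)
  for (ly in names(quota)) {
    cand <- which(lab == ly)
    k <- min(length(cand), quota[[ly]])
    if (k > 0) {
      # optional bias toward the distal edge of each layer band: weight
      # candidates by their axial rank within the layer
      w <- if (within_bias > 0 && length(cand) > 1)
        (rank(zax[cand]) / length(cand))^within_bias else NULL
      picks <- c(picks, sample(cand, k, prob = w))
    }
  }
  sel <- pool[sort(picks), , drop = FALSE]
  if (!is.null(cloud))
    attr(sel, "cloud_rows") <- attr(pool, "cloud_rows")[sort(picks)]
  sel
}
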