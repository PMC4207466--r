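# Hexagonal close packing of spherical somata inside the granule cell layer.

#' Pack somata on a hexagonal grid inside the GCL
#'
#' Spheres of the given diameter are arranged on a hexagonal close-packed
#' lattice with center spacing `diameter + gap`, and every sphere with any
#' portion outside the GCL volume is discarded (centers must lie at least
#' `margin` from all GCL boundaries).  The lattice phase is randomized from
#' the seed; counts are insensitive to the phase at anatomical scale.
#'
#' @param volume a `dg_volume` or toy volume whose `"GCL"` label defines
#'   the packing region
#' @param diameter soma diameter (um)
#' @param gap surface-to-surface separation (um)
#' @param seed integer seed controlling the lattice phase
#' @param margin required distance of sphere centers from the region
#'   boundary; defaults to `diameter / 2` ("fully inside"); set 0 to keep
#'   every sphere whose center is inside
#' @param chunk_layers number of lattice planes processed per batch
#' @return a `soma_set`: data.frame with columns x, y, z (um) and, for
#'   `dg_volume` input, intrinsic u, v, d coordinates.
#' @export
pack_somata <- function(volume, diameter = 12.54, gap = 3.5, seed = 1,
                        margin = NULL, chunk_layers = 12) {
  if (diameter <= 0 || gap <= 0) stop("diameter and gap must be positive")
  if (is.null(margin)) margin <- diameter / 2
  a <- diameter + gap
  bb <- vol_bbox(volume)
  set.seed(seed)
  h <- a * sqrt(3) / 2        # row spacing in plane
  c_z <- a * sqrt(2 / 3)      # plane spacing
  phase <- runif(3) * c(a, h, c_z)
  nz <- floor((bb[2, 3] - bb[1, 3]) / c_z) + 1
  ny <- floor((bb[2, 2] - bb[1, 2]) / h) + 1
  nx <- floor((bb[2, 1] - bb[1, 1]) / a) + 2
  is_dg <- inherits(volume, "dg_volume")
  keep <- vector("list", ceiling(nz / chunk_layers))
  ci <- 1
  for (k0 in seq(0, nz - 1, by = chunk_layers)) {
    ks <- k0:min(k0 + chunk_layers - 1, nz - 1)
    g <- expand.grid(i = -1:(nx - 1), j = -1:(ny - 1), k = ks)
    x <- bb[1, 1] + phase[1] + a * (g$i + 0.5 * (g$j %% 2) + 0.5 * (g$k %% 2))
    y <- bb[1, 2] + phase[2] + h * g$j + (a * sqrt(3) / 6) * (g$k %% 2)
    z <- bb[1, 3] + phase[3] + c_z * g$k
    pts <- cbind(x = x, y = y, z = z)
    keep[[ci]] <- if (is_dg) .pack_filter_dg(volume, pts, margin)
                  else .pack_filter_generic(volume, pts, margin)
    ci <- ci + 1
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out <- as.data.frame(out)
  class(out) <- c("soma_set", "data.frame")
  attr(out, "diameter") <- diameter
  attr(out, "spacing") <- a
  out
}

# exact band test in intrinsic coordinates, with angular end margins
# converted to um through the local metric
.pack_filter_dg <- function(volume, pts, margin) {
  p <- volume$params
  # cheap shell pre-filter
  rxy <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  r_band <- p$A0 * (1 + abs(p$eps_a)) + p$w_gcl + 60
  m <- abs(rxy - p$R) < r_band
  if (!any(m)) return(NULL)
  pts <- pts[m, , drop = FALSE]
  u <- atan2(pts[, 2], pts[, 1])
  u <- ifelse(u < -0.5 * pi, u + 2 * pi, u)
  ze <- pts[, 3] - p$Dz * sin(u)
  m2 <- abs(ze) < p$B0 * (1 + abs(p$eps_b)) + p$w_gcl + 60 &
    u > p$u_range_gcl[1] - 0.02 & u < p$u_range_gcl[2] + 0.02
  if (!any(m2)) return(NULL)
  pts <- pts[m2, , drop = FALSE]
  co <- dg_coords(volume, pts)
  ax <- .dg_axes(p, co$u)
  # local metric factors (um per radian)
  su <- sqrt(pts[, 1]^2 + pts[, 2]^2 + (p$Dz * cos(co$u))^2)
  sv <- sqrt(ax$A^2 * sin(co$v)^2 + ax$B^2 * cos(co$v)^2)
  du <- margin / su
  dv <- margin / sv
  ok <- co$d <= -margin & co$d >= -p$w_gcl + margin &
    co$u >= p$u_range_gcl[1] + du & co$u <= p$u_range_gcl[2] - du &
    co$v >= p$v_range[1] + dv & co$v <= p$v_range[2] - dv
  if (!any(ok)) return(NULL)
  cbind(pts[ok, , drop = FALSE],
        u = co$u[ok], v = co$v[ok], d = co$d[ok])
}

# probe-based margin test for analytic toy volumes
.pack_filter_generic <- function(volume, pts, margin) {
  lab <- classify_points(volume, pts)
  ok <- lab == "GCL"
  if (margin > 0 && any(ok)) {
    probes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * margin
    sub <- which(ok)
    for (i in seq_len(nrow(probes))) {
      shifted <- sweep(pts[sub, , drop = FALSE], 2, probes[i, ], "+")
      ok[sub[classify_points(volume, shifted) != "GCL"]] <- FALSE
      sub <- which(ok)
      if (!length(sub)) break
    }
  }
  if (!any(ok)) return(NULL)
  pts[ok, , drop = FALSE]
}

#' Label somata with anatomical subgroups
#'
#' Adds the normalized GCL depth (0 at the hilar border, 1 at the ML
#' border) and the four-way subgroup label: superficial somata lie in the
#' half of the GCL closest to the ML (`depth >= 0.5`); the blade label
#' splits the transverse "C" at the midpoint of the `v` range, with the
#' suprapyramidal blade on the low-`v` side (ties assigned suprapyramidal).
#'
#' @param somata a `soma_set` from [pack_somata()] on a `dg_volume`
#' @param volume the same `dg_volume`
#' @return the `soma_set` with columns `depth` and `subgroup` added.
#' @export
assign_subgroups <- function(somata, volume) {
  if (is.null(somata$d))
    stop("somata lack intrinsic coordinates; pack on a dg_volume first")
  p <- volume$params
  if (any(somata$d > 0 | somata$d < -p$w_gcl))
    stop("soma outside the GCL band")
  depth <- 1 + somata$d / p$w_gcl
  v_mid <- mean(p$v_range)
  blade <- ifelse(somata$v <= v_mid, "supra", "infra")
  pos <- ifelse(depth >= 0.5, "superficial", "deep")
  somata$depth <- depth
  somata$subgroup <- paste(blade, pos, sep = "_")
  somata
}
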