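# Deterministic small-scale test inputs: analytic toy volumes with
# closed-form volumes/widths, and fixture trees with hand-computable
# morphometrics.

#' Analytic toy volumes
#'
#' Provides simple shapes with closed-form volume that share the volume
#' interface of [build_dg_volume()] (`classify_points`, `vol_bbox`,
#' `boundary_cloud`), so estimators can be validated exactly.
#'
#' * `box`: axis-aligned box centered at the origin, all interior points in
#'   one layer (`dims = c(lx, ly, lz)`).
#' * `shell`: spherical layered shell mimicking the DG laminae: GCL band
#'   `[r0 - w_gcl, r0)`, molecular layer bands splitting `[r0, r0 + w_ml]`
#'   into equal thirds (`dims = c(r0, w_gcl, w_ml)`).
#' * `cone`: elliptical cone, apex at origin, axis +z
#'   (`dims = c(a, b, h)` = base semi-axes and height).
#'
#' @param kind one of `"box"`, `"shell"`, `"cone"`
#' @param dims numeric vector of dimensions (um), see above
#' @param layer layer label assigned to interior points of `box`/`cone`
#' @return object of class `toy_volume` with element `volume_um3`
#'   (closed form; for `shell`, the volume of the selected `layer`).
#' @export
make_toy_volume <- function(kind = c("box", "shell", "cone"),
                            dims, layer = "GCL") {
  kind <- match.arg(kind)
  if (any(dims <= 0)) stop("dimensions must be positive")
  obj <- list(kind = kind, dims = dims, layer = layer)
  if (kind == "box") {
    obj$bbox <- rbind(lo = -dims / 2, hi = dims / 2)
    obj$volume_um3 <- prod(dims)
  } else if (kind == "shell") {
    r1 <- dims[1] + dims[3]
    obj$bbox <- rbind(lo = rep(-r1, 3), hi = rep(r1, 3))
    vol_band <- function(a, b) 4 / 3 * pi * (b^3 - a^3)
    r0 <- dims[1]; w3 <- dims[3] / 3
    obj$volume_um3 <- switch(layer,
      GCL = vol_band(r0 - dims[2], r0),
      IML = vol_band(r0, r0 + w3),
      MML = vol_band(r0 + w3, r0 + 2 * w3),
      OML = vol_band(r0 + 2 * w3, r0 + dims[3]))
  } else {
    obj$bbox <- rbind(lo = c(-dims[1], -dims[2], 0),
                      hi = c(dims[1], dims[2], dims[3]))
    obj$volume_um3 <- pi * dims[1] * dims[2] * dims[3] / 3
  }
  colnames(obj$bbox) <- c("x", "y", "z")
  class(obj) <- "toy_volume"
  obj
}

#' @export
classify_points.toy_volume <- function(volume, pts) {
  pts <- as_xyz(pts)
  d <- volume$dims
  lab <- rep("OUTSIDE", nrow(pts))
  if (volume$kind == "box") {
    inside <- abs(pts[, 1]) <= d[1] / 2 & abs(pts[, 2]) <= d[2] / 2 &
      abs(pts[, 3]) <= d[3] / 2
    lab[inside] <- volume$layer
  } else if (volume$kind == "shell") {
    r <- sqrt(rowSums(pts^2))
    r0 <- d[1]; w3 <- d[3] / 3
    lab[r >= r0 - d[2] & r < r0] <- "GCL"
    lab[r >= r0 & r < r0 + w3] <- "IML"
    lab[r >= r0 + w3 & r < r0 + 2 * w3] <- "MML"
    lab[r >= r0 + 2 * w3 & r <= r0 + d[3]] <- "OML"
  } else {
    z <- pts[, 3]
    inside <- z >= 0 & z <= d[3] &
      (pts[, 1] / d[1])^2 + (pts[, 2] / d[2])^2 <= (z / d[3])^2
    lab[inside] <- volume$layer
  }
  factor(lab, levels = DG_LAYERS)
}

#' @export
vol_bbox.toy_volume <- function(volume) volume$bbox

#' @export
boundary_cloud.toy_volume <- function(volume, L = 3, n = 2e6, seed = 1) {
  if (volume$kind != "shell")
    stop("boundary clouds are only defined for shell toy volumes")
  r <- if (L <= 0) volume$dims[1] else volume$dims[1] + volume$dims[3] * L / 3
  set.seed(seed)
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2)) * r
  colnames(g) <- c("x", "y", "z")
  g
}

#' Fixture trees with known morphometrics
#'
#' Builds small deterministic trees together with a sidecar list of their
#' exact statistics (computed by construction, not by the package's
#' morphometric code), for use as oracles.
#'
#' Templates: `straight` (single unbranched cable), `y` (one bifurcation),
#' `binary` (full binary tree of given depth), `comb` (caterpillar with
#' given number of tips), `gclike` (small hand-built granule-cell-like
#' tree spanning several layers).
#'
#' @param template template name
#' @param depth depth for `binary`
#' @param tips tip count for `comb`
#' @param seg segment length (um) used in construction
#' @return list with elements `tree` (a `morph_tree`) and `expected`
#'   (named list of exact statistics).
#' @export
make_fixture_tree <- function(template = c("straight", "y", "binary",
                                           "comb", "gclike"),
                              depth = 3, tips = 8, seg = 20) {
  template <- match.arg(template)
  if (template == "straight") {
    n <- 6
    xyz <- cbind(0, 0, seq(0, by = seg, length.out = n))
    tree <- morph_tree(xyz, c(0L, seq_len(n - 1)))
    expected <- list(total_length = (n - 1) * seg, n_tips = 1,
                     n_branch_points = 0, n_branches = 1, max_order = 0,
                     asymmetry = NA_real_, contraction = 1)
  } else if (template == "y") {
    # stem 0->(0,0,40), two oblique daughters of length 50 each
    xyz <- rbind(c(0, 0, 0), c(0, 0, 40),
                 c(30, 0, 80), c(-30, 0, 80))
    tree <- morph_tree(xyz, c(0L, 1L, 2L, 2L))
    expected <- list(total_length = 40 + 2 * 50, n_tips = 2,
                     n_branch_points = 1, n_branches = 3, max_order = 1,
                     asymmetry = NA_real_, contraction = 1)
  } else if (template == "binary") {
    # full binary tree; children spread in x halves at each level
    xyz <- list(c(0, 0, 0))
    parent <- list(0L)
    grow <- function(node, x, z, level) {
      if (level > depth) return(invisible())
      for (s in c(-1, 1)) {
        xx <- x + s * seg * 2^(depth - level)
        k <- length(xyz) + 1L          # force now (lazy evaluation)
        xyz[[k]] <<- c(xx, 0, z + seg)
        parent[[k]] <<- node
        grow(k, xx, z + seg, level + 1)
      }
    }
    grow(1L, 0, 0, 1L)
    tree <- morph_tree(do.call(rbind, xyz), unlist(parent))
    n_tips <- 2^depth
    # the root (soma) has two children but is not a branch point, so the
    # level-1 nodes contribute the first counted branch points
    expected <- list(n_tips = n_tips, n_branch_points = 2^depth - 2,
                     n_branches = 2 * 2^depth - 2,
                     max_order = depth - 1, asymmetry = 0)
  } else if (template == "comb") {
    # spine along z, one side tooth at each spine node
    xyz <- list(c(0, 0, 0))
    parent <- list(0L)
    spine <- 1L
    for (i in seq_len(tips - 1)) {
      xyz[[length(xyz) + 1]] <- c(0, 0, i * seg)
      parent[[length(parent) + 1]] <- spine
      spine <- length(xyz)
      xyz[[length(xyz) + 1]] <- c(seg, 0, i * seg)
      parent[[length(parent) + 1]] <- spine
    }
    xyz[[length(xyz) + 1]] <- c(0, 0, tips * seg)
    parent[[length(parent) + 1]] <- spine
    tree <- morph_tree(do.call(rbind, xyz), unlist(parent))
    expected <- list(n_tips = tips, n_branch_points = tips - 1,
                     asymmetry = 1)
  } else {
    # small GC-like tree: soma at origin, two stems, a few bifurcations,
    # nodes roughly radiating in +z with known total length
    xyz <- rbind(
      c(0, 0, 0),                       # 1 soma
      c(10, 0, 30), c(-10, 0, 30),      # 2,3 stems
      c(30, 0, 80), c(0, 5, 90),        # 4,5 children of 2
      c(-25, -5, 85),                   # 6 child of 3 (continuation)
      c(55, 0, 140), c(20, 10, 150),    # 7,8 children of 4
      c(-40, -10, 150), c(-5, -15, 150))# 9,10 children of 6
    parent <- c(0L, 1L, 1L, 2L, 2L, 3L, 4L, 4L, 6L, 6L)
    tree <- morph_tree(xyz, parent, diameter = seq(2, 0.5, length.out = 10),
                       subgroup = "supra_superficial", cell_id = 1L)
    expected <- list(n_tips = 5, n_branch_points = 3, n_stems = 2,
                     n_branches = 8, max_order = 2)
  }
  list(tree = tree, expected = expected)
}
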