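# Population-level, voxel-based analyses: per-cube unique-cell overlap,
# cable length/density, volumetric occupancy, simulated axon complexity,
# and surface maps over the granule cell layer.

#' Build a voxel occupancy grid
#'
#' Bins dendritic segments into cubes of the given edge length using the
#' segment center (trees should be resampled at a fixed interval, so the
#' per-cube length and volume sums are approximations at that
#' resolution).  Only cubes whose centers classify into the requested
#' layers are retained.
#'
#' @param trees list of `morph_tree` objects
#' @param volume the `dg_volume` (used to restrict cubes to the ML)
#' @param edge cube edge (um)
#' @param layers layers whose cubes are kept
#' @param slice optional predicate restricting segments to a slab
#' @param min_cells drop cubes with fewer unique cells (edge cubes)
#' @return `occupancy_grid`: data.frame with cube indices i, j, k, center
#'   coordinates, `n_cells`, `length_um`, `density` (um/um^3),
#'   `occupancy_pct`, and the cube `layer`.
#' @export
build_grid <- function(trees, volume, edge = 25,
                       layers = c("IML", "MML", "OML"), slice = NULL,
                       min_cells = 1) {
  segs <- lapply(trees, function(tr) {
    n <- nrow(tr$xyz)
    if (n < 2) return(NULL)
    i <- 2:n
    mid <- (tr$xyz[i, , drop = FALSE] + tr$xyz[tr$parent[i], , drop = FALSE]) / 2
    el <- edge_lengths(tr)[i]
    rad <- (tr$diameter[i] + tr$diameter[tr$parent[i]]) / 4  # mean radius
    keep <- rep(TRUE, length(el))
    if (!is.null(slice)) keep <- slice(mid)
    if (!any(keep)) return(NULL)
    data.frame(x = mid[keep, 1], y = mid[keep, 2], z = mid[keep, 3],
               len = el[keep], vol = pi * rad[keep]^2 * el[keep],
               cell = tr$cell_id)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0) stop("no segments to bin")
  ijk <- floor(cbind(segs$x, segs$y, segs$z) / edge)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  agg <- function(v, f) tapply(v, key, f)
  cells <- tapply(segs$cell, key, function(cc) length(unique(cc)))
  lens <- agg(segs$len, sum)
  vols <- agg(segs$vol, sum)
  kk <- names(cells)
  ix <- do.call(rbind, strsplit(kk, " "))
  ix <- matrix(as.integer(ix), ncol = 3)
  centers <- (ix + 0.5) * edge
  lay <- as.character(classify_points(volume, centers))
  keep <- lay %in% layers & cells >= min_cells
  g <- data.frame(i = ix[keep, 1], j = ix[keep, 2], k = ix[keep, 3],
                  x = centers[keep, 1], y = centers[keep, 2],
                  z = centers[keep, 3],
                  n_cells = as.integer(cells[keep]),
                  length_um = as.numeric(lens[keep]),
                  density = as.numeric(lens[keep]) / edge^3,
                  occupancy_pct = 100 * as.numeric(vols[keep]) / edge^3,
                  layer = lay[keep], stringsAsFactors = FALSE)
  rownames(g) <- NULL
  attr(g, "edge") <- edge
  class(g) <- c("occupancy_grid", "data.frame")
  g
}

#' Simulated axon complexity for one cube
#'
#' Estimates the branching complexity an axon needs to contact every
#' granule cell dendrite present in a cube: random points in the cube are
#' connected by the optimal-wiring rule with balancing factor zero
#' (minimum total length), and the number of points is increased until the
#' resampled axon passes within `reach` of a dendritic node of every cell;
#' branch-point counts are averaged over `n_repeats` random collections.
#'
#' @param cube_center length-3 center of the cube (um)
#' @param trees list of `morph_tree` whose dendrites enter the cube
#' @param edge cube edge (um)
#' @param reach contact distance (um)
#' @param n_repeats number of random collections averaged
#' @param increment target points added per round
#' @param seed integer seed
#' @param max_points safety cap on the number of axon target points
#' @return list with `mean_branch_points`, per-repeat counts, and the
#'   per-repeat numbers of target points used.
#' @export
axon_complexity <- function(cube_center, trees, edge = 25, reach = 5,
                            n_repeats = 10, increment = 5, seed = 1,
                            max_points = 400) {
  # dendritic nodes of each cell near the cube (margin = reach)
  lo <- cube_center - edge / 2 - reach
  hi <- cube_center + edge / 2 + reach
  node_sets <- lapply(trees, function(tr) {
    m <- tr$xyz
    keep <- m[, 1] >= lo[1] & m[, 1] <= hi[1] &
            m[, 2] >= lo[2] & m[, 2] <= hi[2] &
            m[, 3] >= lo[3] & m[, 3] <= hi[3]
    m[keep, , drop = FALSE]
  })
  node_sets <- node_sets[vapply(node_sets, nrow, integer(1)) > 0]
  if (!length(node_sets)) stop("no dendrites present in the cube")
  set.seed(seed)
  bp <- integer(n_repeats)
  npts <- integer(n_repeats)
  for (r in seq_len(n_repeats)) {
    pts <- matrix(numeric(0), 0, 3)
    repeat {
      add <- matrix(runif(3 * increment, -edge / 2, edge / 2),
                    ncol = 3, byrow = FALSE)
      pts <- rbind(pts, sweep(add, 2, cube_center, "+"))
      axon <- grow_tree(cube_center, pts, bf = 0)
      dense <- resample_tree(axon, spacing = 1)
      ok <- all(vapply(node_sets, function(ns)
        min(.min_crossdist(ns, dense$xyz)) <= reach, logical(1)))
      if (ok || nrow(pts) >= max_points) break
    }
    bp[r] <- branch_stats(axon)$n_branch_points
    npts[r] <- nrow(pts)
  }
  list(mean_branch_points = mean(bp), branch_points = bp,
       n_points = npts)
}

#' Correlations between occupancy measures
#'
#' Pearson correlations between the per-cube unique-cell count, cable
#' density and volumetric occupancy.
#'
#' @param grid an `occupancy_grid`
#' @return named numeric: `count_density`, `count_occupancy`,
#'   `density_occupancy`.
#' @export
occupancy_correlations <- function(grid) {
  if (nrow(grid) < 10) stop("need at least 10 cubes")
  c(count_density = cor(grid$n_cells, grid$density),
    count_occupancy = cor(grid$n_cells, grid$occupancy_pct),
    density_occupancy = cor(grid$density, grid$occupancy_pct))
}

#' Map a per-cell statistic onto the granule cell layer surface
#'
#' Triangulates a GCL boundary shell, assigns every cell to its nearest
#' face (by face centroid), and averages the statistic over the cells of
#' each face, stratified by somatic depth class.
#'
#' @param trees list of `morph_tree` objects
#' @param volume a `dg_volume`
#' @param statistic `"total_length"` or `"max_tip_distance"`
#' @param n_faces approximate face count of the triangulation
#' @param L which GCL shell to triangulate (0 = outer, -1.95 = inner)
#' @return data.frame per (face, depth class): face id, mean statistic,
#'   cell count; the mesh is attached as attribute `"mesh"`.
#' @export
surface_map <- function(trees, volume, statistic = c("total_length",
                                                     "max_tip_distance"),
                        n_faces = 5000, L = 0) {
  statistic <- match.arg(statistic)
  mesh <- boundary_mesh(volume, L = L, n_faces = n_faces)
  somata <- do.call(rbind, lapply(trees, function(tr) tr$xyz[1, ]))
  nn <- .nn_grid(somata, mesh$centroids, cell_size = 200)
  val <- vapply(trees, function(tr) {
    if (statistic == "total_length") total_length(tr)
    else {
      tips <- tr$xyz[n_children(tr) == 0L, , drop = FALSE]
      if (!nrow(tips)) 0 else
        max(sqrt(rowSums(sweep(tips, 2, tr$xyz[1, ])^2)))
    }
  }, numeric(1))
  depth <- vapply(trees, function(tr)
    ifelse(grepl("superficial", tr$subgroup %||% ""), "superficial", "deep"),
    character(1))
  df <- data.frame(face = nn$index, value = val, depth = depth)
  out <- do.call(rbind, lapply(split(df, list(df$face, df$depth), drop = TRUE),
    function(d) data.frame(face = d$face[1], depth = d$depth[1],
                           mean_value = mean(d$value), n = nrow(d))))
  rownames(out) <- NULL
  attr(out, "mesh") <- mesh
  attr(out, "statistic") <- statistic
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Layer-mean occupancy profile
#'
#' Mean cable density and volumetric occupancy per molecular sublayer,
#' for checking the laminar gradients (density rising, occupancy falling
#' from IML to OML).
#'
#' @param grid an `occupancy_grid`
#' @return data.frame with one row per layer.
#' @export
layer_profile <- function(grid) {
  sp <- split(grid, factor(grid$layer, levels = c("IML", "MML", "OML")))
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    n_cubes = nrow(d),
    mean_cells = mean(d$n_cells),
    mean_density = mean(d$density),
    mean_occupancy = mean(d$occupancy_pct))))
  out$layer <- rownames(out)
  out
}
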