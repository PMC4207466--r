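# Greedy optimal-wiring growth of a single dendritic tree, plus the
# post-processing stages: 5 um resampling, two-scale spatial jitter, and
# quadratic diameter taper.
#
# The wiring rule attaches, at every step, the unconnected target t that
# minimizes  cost(t) = min over tree nodes n of  ||t - n|| + bf * pl(n),
# where pl(n) is the path length from the root to n.  bf = 0 reduces to
# Prim's minimum spanning tree; larger bf trades total cable for shorter
# somatic paths.

#' Grow a tree through target points by greedy optimal wiring
#'
#' @param root length-3 numeric: the soma position (um)
#' @param targets m x 3 matrix of target points
#' @param bf balancing factor (>= 0); both cost terms are in um
#' @param stems optional integer vector of target indices to attach
#'   directly to the root before greedy growth; afterwards the root is
#'   closed, so its degree equals `length(stems)`
#' @param max_reach maximum connection distance (um): targets farther than
#'   this from every tree node are ineligible until the tree grows toward
#'   them (if no target is within reach, the cheapest unrestricted
#'   attachment is made so growth always completes).  The default `Inf`
#'   is the pure greedy rule; a finite value reproduces the
#'   frontier-limited growth of reference optimal-wiring implementations,
#'   which is what makes balancing factors above 1 produce branched
#'   rather than star-shaped trees.  With `bf = 0` the result is the
#'   minimum spanning tree for any `max_reach`.
#' @return a `morph_tree` (topology and coordinates only; unit diameters).
#'   Node order is root first, then targets in attachment order.
#' @export
grow_tree <- function(root, targets, bf = 0, stems = NULL, max_reach = Inf) {
  if (bf < 0) stop("bf must be non-negative")
  targets <- as_xyz(targets)
  m <- nrow(targets)
  if (m == 0) {
    warning("no target points; returning soma-only stub")
    return(morph_tree(matrix(root, 1), 0L))
  }
  xyz <- matrix(NA_real_, m + 1, 3)
  xyz[1, ] <- root
  parent <- integer(m + 1)
  pl <- numeric(m + 1)
  attached <- logical(m)          # per target
  node_of <- integer(m)           # target -> node index
  # distances and cost of attaching each unattached target at a node
  dists_from <- function(node_xyz) {
    sqrt((targets[, 1] - node_xyz[1])^2 +
         (targets[, 2] - node_xyz[2])^2 +
         (targets[, 3] - node_xyz[3])^2)
  }
  # best eligible (within max_reach) and best unrestricted attachment,
  # both maintained incrementally as pmin over the growing node set
  d0 <- dists_from(root)
  best_cost <- ifelse(d0 <= max_reach, d0, Inf)
  best_par <- rep(1L, m)
  any_cost <- d0
  any_par <- rep(1L, m)
  attach <- function(t_idx, par_node) {
    k <- sum(attached) + 2L        # new node index
    xyz[k, ] <<- targets[t_idx, ]
    parent[k] <<- par_node
    pl[k] <<- pl[par_node] +
      sqrt(sum((targets[t_idx, ] - xyz[par_node, ])^2))
    attached[t_idx] <<- TRUE
    node_of[t_idx] <<- k
    best_cost[t_idx] <<- Inf
    any_cost[t_idx] <<- Inf
    k
  }
  update_costs <- function(k) {
    d <- dists_from(xyz[k, ])
    cand <- d + bf * pl[k]
    better <- !attached & cand < any_cost
    any_cost[better] <<- cand[better]
    any_par[better] <<- k
    better <- !attached & cand < best_cost & d <= max_reach
    best_cost[better] <<- cand[better]
    best_par[better] <<- k
  }
  if (!is.null(stems)) {
    stems <- unique(as.integer(stems))
    if (any(stems < 1 | stems > m)) stop("stem index out of range")
    for (s in stems) {
      k <- attach(s, 1L)
    }
    # close the root: recompute best over the stem nodes only
    best_cost[!attached] <- Inf
    best_par[!attached] <- NA_integer_
    any_cost[!attached] <- Inf
    any_par[!attached] <- NA_integer_
    for (k in 1L + seq_along(stems)) update_costs(k)
  }
  while (!all(attached)) {
    t_idx <- if (all(is.infinite(best_cost))) which.min(any_cost)
             else which.min(best_cost)     # ties: lowest index
    par <- if (is.finite(best_cost[t_idx])) best_par[t_idx]
           else any_par[t_idx]
    k <- attach(t_idx, par)
    update_costs(k)
  }
  morph_tree(xyz, parent)
}

#' Choose initial stem targets
#'
#' Returns the indices of the `n_stems` targets closest to the soma, used
#' as forced first attachments so that the root degree equals the sampled
#' stem count.
#'
#' @param root soma position
#' @param targets target matrix
#' @param n_stems number of stems (1..4)
#' @export
init_stems <- function(root, targets, n_stems) {
  if (n_stems < 1 || n_stems > 4) stop("n_stems must be in 1..4")
  targets <- as_xyz(targets)
  n_stems <- min(n_stems, nrow(targets))
  d <- sqrt(rowSums(sweep(targets, 2, root)^2))
  order(d)[seq_len(n_stems)]
}

#' Resample a tree to a fixed segment interval
#'
#' Re-parameterizes every branch (path between topological points) at a
#' fixed arc-length spacing, preserving branch and termination point
#' positions exactly.
#'
#' @param tree a `morph_tree`
#' @param spacing segment interval (um)
#' @return resampled `morph_tree`.
#' @export
resample_tree <- function(tree, spacing = 5) {
  branches <- tree_branches(tree)
  new_xyz <- list(tree$xyz[1, , drop = FALSE])
  new_parent <- list(0L)
  n_new <- 1L
  new_idx <- integer(nrow(tree$xyz))   # old topological node -> new index
  new_idx[1] <- 1L
  for (br in branches) {
    pts <- tree$xyz[br, , drop = FALSE]
    seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
    arc <- c(0, cumsum(seglen))
    len <- arc[length(arc)]
    np <- max(1L, round(len / spacing))
    if (len <= 0) {
      xi <- pts[nrow(pts), , drop = FALSE]   # degenerate (coincident points)
    } else {
      s_new <- len * seq_len(np) / np
      keep <- c(TRUE, diff(arc) > 0)         # drop zero-length subsegments
      # linear interpolation along the polyline
      xi <- vapply(1:3, function(j)
        stats::approx(arc[keep], pts[keep, j], xout = s_new)$y, numeric(np))
      if (np == 1L) xi <- matrix(xi, 1)
    }
    xi[np, ] <- pts[nrow(pts), ]       # distal endpoint exact
    par <- c(new_idx[br[1]], n_new + seq_len(np - 1L))
    new_xyz[[length(new_xyz) + 1]] <- xi
    new_parent[[length(new_parent) + 1]] <- par
    n_new <- n_new + np
    new_idx[br[length(br)]] <- n_new
  }
  morph_tree(do.call(rbind, new_xyz), unlist(new_parent),
             subgroup = tree$subgroup, cell_id = tree$cell_id,
             meta = tree$meta)
}

# smooth unit-variance noise along arc positions s (Gaussian kernel with
# standard deviation lambda), independent per column
.smooth_noise <- function(s, lambda, ncol = 3) {
  m <- length(s)
  w <- exp(-outer(s, s, "-")^2 / (2 * lambda^2))
  norm <- sqrt(rowSums(w^2))
  (w %*% matrix(rnorm(m * ncol), m, ncol)) / norm
}

#' Apply low-pass filtered spatial jitter
#'
#' Adds per-branch Gaussian displacement fields smoothed along arc length
#' at two length constants, reproducing the tortuosity of biological
#' dendrites.  Topology, diameters and the root position are unchanged;
#' branch endpoints move with their branches.
#'
#' @param tree a resampled `morph_tree`
#' @param amplitudes displacement amplitudes (um), one per length constant
#' @param length_constants smoothing length constants (um)
#' @param seed optional integer seed
#' @return jittered `morph_tree`.
#' @export
apply_jitter <- function(tree, amplitudes = c(2.5, 7),
                         length_constants = c(10, 50), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (all(amplitudes == 0)) return(tree)
  disp <- matrix(0, nrow(tree$xyz), 3)
  pd <- path_dists(tree)
  for (br in tree_branches(tree)) {
    s <- pd[br] - pd[br[1]]
    for (i in seq_along(length_constants)) {
      if (amplitudes[i] == 0) next
      g <- .smooth_noise(s, length_constants[i])
      disp[br[-1], ] <- disp[br[-1], ] + amplitudes[i] * g[-1, , drop = FALSE]
    }
  }
  disp[1, ] <- 0
  out <- tree
  out$xyz <- tree$xyz + disp
  out
}

#' Apply diameter taper
#'
#' Diameter decreases as a quadratic function of path distance from the
#' soma, `d(x) = d_tip + (d_max - d_tip) (1 - x/X)^2` with `X` the longest
#' path in the cell, modulated near the soma by the scaling
#' `min(1, exp(x/lambda) - 1)` which shapes the steep initial taper just
#' outside the soma.  The root keeps the soma diameter.
#'
#' @param tree a `morph_tree`
#' @param d_max proximal dendrite diameter (um)
#' @param d_tip tip diameter (um)
#' @param lambda length constant (um) of the near-soma scaling
#' @param d_min floor diameter (um); results below it are clamped with a
#'   warning
#' @param soma_diameter diameter assigned to the root node
#' @return `morph_tree` with diameters set.
#' @export
apply_taper <- function(tree, d_max = 2.2, d_tip = 0.75, lambda = 5,
                        d_min = 0.3, soma_diameter = 12.54) {
  x <- path_dists(tree)
  X <- max(x)
  d <- d_tip + (d_max - d_tip) * (1 - x / X)^2
  d <- d * pmin(1, exp(x / lambda) - 1)
  if (any(d[-1] < d_min))
    warning("clamping ", sum(d[-1] < d_min), " diameters to ", d_min, " um")
  d <- pmax(d, d_min)
  d[1] <- soma_diameter
  out <- tree
  out$diameter <- d
  out
}

# deterministic per-cell seed derived from the master seed
cell_seed <- function(master_seed, cell_id) {
  as.integer((as.numeric(master_seed) + as.numeric(cell_id) * 48271) %%
               2147483647)
}

#' Generate one complete granule cell
#'
#' Runs the full per-cell pipeline: parameter draws, cone orientation,
#' target-point selection, optimal-wiring growth with forced stems, 5 um
#' resampling, two-scale jitter, diameter taper and layer tagging.
#' Deterministic given (cell id, master seed).
#'
#' @param volume a `dg_volume`
#' @param soma one-row `soma_set` with subgroup labels
#'   (see [assign_subgroups()])
#' @param cell_id integer id of the cell
#' @param master_seed master seed of the run
#' @param tab subgroup parameter table
#' @param oml_cloud OML boundary cloud for cone orientation
#' @param cloud optional shared `target_cloud` (marks points unavailable)
#' @param resample_spacing segment interval (um)
#' @return a `morph_tree` with layers tagged and diameters mapped.
#' @export
generate_cell <- function(volume, soma, cell_id, master_seed = 1,
                          tab = default_subgroup_params(),
                          oml_cloud = NULL, cloud = NULL,
                          resample_spacing = 5) {
  if (is.null(oml_cloud))
    oml_cloud <- boundary_cloud(volume, L = 3, n = 2e5, seed = 1)
  set.seed(cell_seed(master_seed, cell_id))
  sg <- soma$subgroup[1]
  row <- tab[sg, ]
  if (is.na(row$bf)) stop("soma has no known subgroup label")
  n_stems <- rtrunc_pois(1, row$stem_lambda)
  rt <- max(30, rnorm(1, row$rt_mean, row$rt_sd))
  rl <- max(20, rt * row$rl_ratio)
  ao <- if (is.null(row$apex_offset)) 0 else row$apex_offset
  cone <- orient_cone(volume, soma, oml_cloud, rt = rt, rl = rl,
                      apex_offset = ao)
  quota <- draw_quota(sg, tab)
  ze <- if (is.null(row$z_exp)) 3 else row$z_exp
  wb <- if (is.null(row$within_bias)) 0 else row$within_bias
  targets <- select_targets(volume, cone, quota, cloud = cloud, z_exp = ze,
                            within_bias = wb)
  root <- cone$soma
  if (nrow(targets) == 0) {
    warning("cell ", cell_id, ": empty target set; soma-only stub")
    return(morph_tree(matrix(root, 1), 0L, subgroup = sg,
                      cell_id = cell_id))
  }
  stems <- init_stems(root, targets, n_stems)
  mr <- if (is.null(row$max_reach)) Inf else row$max_reach
  tree <- grow_tree(root, targets, bf = row$bf, stems = stems,
                    max_reach = mr)
  tree$subgroup <- sg
  tree$cell_id <- cell_id
  tree$meta <- list(cone = cone, n_stems = length(stems), quota = quota,
                    bf = row$bf)
  tree <- resample_tree(tree, spacing = resample_spacing)
  tree <- apply_jitter(tree, amplitudes = c(row$amp10, row$amp50),
                       length_constants = c(10, 50))
  d_max <- max(1.2, rnorm(1, row$dmax_mean, row$dmax_sd))
  d_tip <- max(0.4, rnorm(1, row$dtip_mean, row$dtip_sd))
  tree <- apply_taper(tree, d_max = d_max, d_tip = d_tip,
                      lambda = row$taper_lambda,
                      soma_diameter = volume$params$soma_diameter)
  tree$layer <- as.character(classify_points(volume, tree$xyz))
  tree
}

#' Generate a population of granule cells
#'
#' @param volume a `dg_volume`
#' @param somata a labeled `soma_set`
#' @param cell_ids which somata to grow (row indices); defaults to all
#' @param master_seed master seed
#' @param tab subgroup parameter table
#' @param oml_cloud_n size of the OML boundary cloud used for cone
#'   orientation
#' @param progress print progress every that many cells (0 = silent)
#' @return list of `morph_tree` objects.
#' @export
generate_population <- function(volume, somata, cell_ids = NULL,
                                master_seed = 1,
                                tab = default_subgroup_params(),
                                oml_cloud_n = 2e5, progress = 0) {
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(somata))
  oml_cloud <- boundary_cloud(volume, L = 3, n = oml_cloud_n, seed = 1)
  out <- vector("list", length(cell_ids))
  for (i in seq_along(cell_ids)) {
    id <- cell_ids[i]
    out[[i]] <- generate_cell(volume, somata[id, ], cell_id = id,
                              master_seed = master_seed, tab = tab,
                              oml_cloud = oml_cloud)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  grew %d / %d cells", i, length(cell_ids)))
  }
  out
}
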