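# Single-cell and population morphometrics used for validation: Sholl
# profiles, branch contraction, branch counts and orders, partition
# asymmetry, dendritic-field spreads, laminar distributions, and
# population summaries with subgroup contrasts.

#' Sholl analysis
#'
#' Counts intersections of the dendrite with concentric spheres centered
#' on the root.  An edge crossing a sphere k times contributes k (straight
#' segments cross at most twice; the usual case is one sign change of the
#' radial distance along the edge).
#'
#' @param tree a `morph_tree`
#' @param step sphere radius increment (um)
#' @param radii optional explicit radii vector (overrides `step`)
#' @return data.frame with columns `radius`, `crossings`.
#' @export
sholl <- function(tree, step = 20, radii = NULL) {
  r0 <- sqrt(rowSums(sweep(tree$xyz, 2, tree$xyz[1, ])^2))
  if (is.null(radii))
    radii <- seq(step, max(r0) + step, by = step)
  i <- 2:nrow(tree$xyz)
  ra <- r0[tree$parent[i]]
  rb <- r0[i]
  lo <- pmin(ra, rb); hi <- pmax(ra, rb)
  crossings <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  data.frame(radius = radii, crossings = crossings)
}

#' Branch contraction
#'
#' Ratio of Euclidean to path distance between the endpoints of every
#' branch (path between topological points); 1 for perfectly straight
#' branches.
#'
#' @param tree a `morph_tree`
#' @return numeric vector of per-branch contraction values in (0, 1].
#' @export
contraction <- function(tree) {
  pd <- path_dists(tree)
  vapply(tree_branches(tree), function(br) {
    a <- br[1]; b <- br[length(br)]
    eu <- sqrt(sum((tree$xyz[b, ] - tree$xyz[a, ])^2))
    pa <- pd[b] - pd[a]
    if (pa == 0) 1 else min(1, eu / pa)
  }, numeric(1))
}

#' Branch statistics
#'
#' Branches are paths between topological points (root, branch points,
#' tips).  Branch order of a node is the number of branch points on the
#' path from the root (stems have order 0).  Intermediate branches end in
#' a branch point; terminal branches end in a tip.
#'
#' @param tree a `morph_tree`
#' @return list with counts, max branch order, total length, and mean
#'   intermediate/terminal branch lengths (um).
#' @export
branch_stats <- function(tree) {
  n <- nrow(tree$xyz)
  role <- node_roles(tree)
  nc <- n_children(tree)
  if (n == 1)
    return(list(n_stems = 0L, n_branch_points = 0L, n_tips = 0L,
                n_branches = 0L, max_order = 0L, total_length = 0,
                mean_intermediate_length = NA_real_,
                mean_terminal_length = NA_real_, soma_only = TRUE))
  pd <- path_dists(tree)
  branches <- tree_branches(tree)
  blen <- vapply(branches, function(br) pd[br[length(br)]] - pd[br[1]],
                 numeric(1))
  terminal <- vapply(branches, function(br) role[br[length(br)]] == "tip",
                     logical(1))
  # branch order: count branch points above each node
  ord <- integer(n)
  is_bp <- role == "branch"
  for (i in 2:n) ord[i] <- ord[tree$parent[i]] + as.integer(is_bp[tree$parent[i]])
  list(n_stems = nc[1],
       n_branch_points = sum(is_bp),
       n_tips = sum(role == "tip"),
       n_branches = length(branches),
       max_order = max(ord),
       total_length = total_length(tree),
       mean_intermediate_length = if (any(!terminal)) mean(blen[!terminal])
                                  else NA_real_,
       mean_terminal_length = if (any(terminal)) mean(blen[terminal])
                              else NA_real_,
       mean_path_to_tips = mean(pd[nc == 0]),
       soma_only = FALSE)
}

#' Topological (partition) asymmetry
#'
#' Mean over branch points of `|l - r| / (l + r - 2)` where l and r are
#' the tip counts of the two daughter subtrees; degree-2 partitions
#' (`l + r = 2`, a terminal cherry) are undefined and excluded from the
#' mean, so a comb (caterpillar) tree of any size scores exactly 1.  At
#' multifurcations the mean over the defined daughter pairs is used.  The
#' root (soma) is not a branch point.
#'
#' @param tree a `morph_tree`
#' @return asymmetry index in [0, 1]; NA if the tree has no branch point.
#' @export
asymmetry <- function(tree) {
  role <- node_roles(tree)
  bps <- which(role == "branch")
  if (!length(bps)) return(NA_real_)
  tips <- subtree_tips(tree)
  kids <- split(seq_len(nrow(tree$xyz))[-1], tree$parent[-1])
  vals <- vapply(bps, function(b) {
    tt <- tips[kids[[as.character(b)]]]
    prs <- utils::combn(length(tt), 2)
    v <- vapply(seq_len(ncol(prs)), function(j) {
      l <- tt[prs[1, j]]; r <- tt[prs[2, j]]
      if (l + r <= 2) NA_real_ else abs(l - r) / (l + r - 2)
    }, numeric(1))
    mean(v, na.rm = TRUE)          # NaN if every pair is degree-2
  }, numeric(1))
  vals <- vals[is.finite(vals)]    # branch points with no valid partition
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Dendritic-field spreads
#'
#' Extent between the outermost dendritic tips along the transverse and
#' longitudinal axes.  By default the transverse axis is the principal
#' direction of the tip coordinates projected into the plane orthogonal
#' to the cell's cone axis (granule cells spread widest transversely);
#' with `frame = "cone"` the stored cone frame axes are used directly.
#'
#' @param tree a `morph_tree` grown by [generate_cell()] (its cone frame
#'   is stored in `meta`), or any tree if `axes` is supplied
#' @param frame `"pca"` (default) or `"cone"`
#' @param axes optional list with unit vectors `t_hat`, `l_hat` overriding
#'   the stored frame
#' @return named numeric: `transverse`, `longitudinal` (um).
#' @export
spreads <- function(tree, frame = c("pca", "cone"), axes = NULL) {
  frame <- match.arg(frame)
  tips <- tree$xyz[n_children(tree) == 0L, , drop = FALSE]
  if (nrow(tips) < 2) return(c(transverse = 0, longitudinal = 0))
  if (is.null(axes)) {
    cone <- tree$meta$cone
    if (is.null(cone)) stop("tree carries no cone frame; supply `axes`")
    axes <- list(t_hat = cone$t_hat, l_hat = cone$l_hat, axis = cone$axis)
  }
  if (frame == "pca" && nrow(tips) >= 3) {
    w <- sweep(tips, 2, colMeans(tips))
    # project tips into the plane orthogonal to the cone axis
    pt <- cbind(w %*% axes$t_hat, w %*% axes$l_hat)
    e <- eigen(stats::cov(pt), symmetric = TRUE)
    a1 <- e$vectors[, 1]
    t_dir <- a1[1] * axes$t_hat + a1[2] * axes$l_hat
    l_dir <- -a1[2] * axes$t_hat + a1[1] * axes$l_hat
  } else {
    t_dir <- axes$t_hat
    l_dir <- axes$l_hat
  }
  pt <- tips %*% t_dir
  pl <- tips %*% l_dir
  c(transverse = max(pt) - min(pt), longitudinal = max(pl) - min(pl))
}

#' Laminar distribution of branch points and dendritic length
#'
#' Segment lengths are attributed to the layer of the segment midpoint;
#' branch points to the layer of the node.  Following the reference
#' convention, GCL counts and lengths are folded into the IML column.
#'
#' @param tree a `morph_tree`
#' @param volume the `dg_volume` used to classify midpoints (omit to use
#'   stored per-node layer tags for both nodes and segments)
#' @return data.frame with rows IML, MML, OML and columns
#'   `pct_branch_points`, `pct_length`.
#' @export
laminar_distribution <- function(tree, volume = NULL) {
  n <- nrow(tree$xyz)
  i <- 2:n
  mids <- (tree$xyz[i, , drop = FALSE] +
           tree$xyz[tree$parent[i], , drop = FALSE]) / 2
  if (!is.null(volume)) {
    seg_layer <- as.character(classify_points(volume, mids))
    node_layer <- as.character(classify_points(volume, tree$xyz))
  } else {
    if (all(is.na(tree$layer))) stop("tree has no layer tags")
    node_layer <- tree$layer
    seg_layer <- node_layer[i]     # midpoint approximated by distal node
  }
  fold <- function(l) ifelse(l == "GCL", "IML", l)
  seg_layer <- fold(seg_layer)
  node_layer <- fold(node_layer)
  el <- edge_lengths(tree)[i]
  role <- node_roles(tree)
  lay <- c("IML", "MML", "OML")
  len <- vapply(lay, function(L) sum(el[seg_layer == L]), numeric(1))
  bp <- vapply(lay, function(L)
    sum(role == "branch" & node_layer == L), numeric(1))
  data.frame(layer = lay,
             pct_branch_points = if (sum(bp) > 0) 100 * bp / sum(bp) else 0 * bp,
             pct_length = if (sum(len) > 0) 100 * len / sum(len) else 0 * len,
             row.names = lay)
}

#' Full morphometric report for one cell
#'
#' @param tree a `morph_tree`
#' @param volume optional `dg_volume` for laminar classification
#' @param sholl_step Sholl radius step (um)
#' @return one-row data.frame of the cell's statistics.
#' @export
cell_report <- function(tree, volume = NULL, sholl_step = 20) {
  bs <- branch_stats(tree)
  lam <- tryCatch(laminar_distribution(tree, volume),
                  error = function(e) NULL)
  sp <- tryCatch(spreads(tree), error = function(e)
    c(transverse = NA_real_, longitudinal = NA_real_))
  data.frame(
    cell_id = tree$cell_id, subgroup = tree$subgroup,
    n_stems = bs$n_stems, n_branches = bs$n_branches,
    n_branch_points = bs$n_branch_points, n_tips = bs$n_tips,
    max_order = bs$max_order, total_length = bs$total_length,
    mean_path_to_tips = bs$mean_path_to_tips,
    mean_intermediate_length = bs$mean_intermediate_length,
    mean_terminal_length = bs$mean_terminal_length,
    asymmetry = asymmetry(tree),
    mean_contraction = mean(contraction(tree)),
    transverse_spread = sp[["transverse"]],
    longitudinal_spread = sp[["longitudinal"]],
    pct_bp_iml = if (is.null(lam)) NA_real_ else lam["IML", "pct_branch_points"],
    pct_bp_mml = if (is.null(lam)) NA_real_ else lam["MML", "pct_branch_points"],
    pct_bp_oml = if (is.null(lam)) NA_real_ else lam["OML", "pct_branch_points"],
    pct_len_iml = if (is.null(lam)) NA_real_ else lam["IML", "pct_length"],
    pct_len_mml = if (is.null(lam)) NA_real_ else lam["MML", "pct_length"],
    pct_len_oml = if (is.null(lam)) NA_real_ else lam["OML", "pct_length"],
    stringsAsFactors = FALSE)
}

#' Population summary with subgroup contrasts
#'
#' Per-cell reports aggregated to mean +/- sd overall, per blade and per
#' subgroup, with Welch two-sample t-tests for the suprapyramidal versus
#' infrapyramidal contrast of each measure.
#'
#' @param trees list of `morph_tree` objects
#' @param volume optional `dg_volume` for laminar statistics
#' @return list with `cells` (per-cell data.frame), `overall`,
#'   `by_subgroup` (mean and sd tables), and `tests` (t statistics and
#'   p-values supra vs infra).
#' @export
population_summary <- function(trees, volume = NULL) {
  cells <- do.call(rbind, lapply(trees, cell_report, volume = volume))
  num <- cells[, vapply(cells, is.numeric, logical(1))]
  num$cell_id <- NULL
  overall <- data.frame(mean = colMeans(num, na.rm = TRUE),
                        sd = apply(num, 2, sd, na.rm = TRUE))
  blade <- ifelse(grepl("^supra", cells$subgroup), "supra", "infra")
  by_sg <- lapply(split(num, cells$subgroup), function(d)
    data.frame(mean = colMeans(d, na.rm = TRUE),
               sd = apply(d, 2, sd, na.rm = TRUE)))
  tests <- NULL
  if (length(unique(blade)) == 2 && min(table(blade)) >= 2) {
    tests <- do.call(rbind, lapply(names(num), function(v) {
      a <- num[[v]][blade == "supra"]; b <- num[[v]][blade == "infra"]
      tt <- tryCatch(t.test(a, b), error = function(e) NULL)
      if (is.null(tt))                 # constant or all-NA data
        return(data.frame(measure = v, t = NA_real_, p = NA_real_,
                          degenerate = TRUE))
      data.frame(measure = v, t = unname(tt$statistic), p = tt$p.value,
                 degenerate = FALSE)
    }))
  }
  list(cells = cells, overall = overall, by_subgroup = by_sg, tests = tests)
}

#' Convert a reported standard error to a standard deviation
#'
#' The conventional conversion multiplies the standard error by the
#' square root of the sample size.  The reference methods text states the
#' conversion as multiplication by the sample size itself; that verbatim
#' variant is available behind `exact_text = TRUE`.
#'
#' @param se standard error
#' @param n sample size
#' @param exact_text use the verbatim (se * n) form
#' @export
sd_from_se <- function(se, n, exact_text = FALSE) {
  if (exact_text) se * n else se * sqrt(n)
}
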