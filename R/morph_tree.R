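# Rooted morphology container. Nodes are stored in topological order
# (parent index strictly less than child index; root first, parent = 0),
# which keeps path accumulations simple and vectorized.

#' Construct a rooted morphology tree
#'
#' @param xyz n x 3 matrix of node coordinates (um)
#' @param parent integer vector of parent indices (root has parent 0)
#' @param diameter node diameters (um); defaults to 1
#' @param layer optional per-node layer labels
#' @param subgroup optional subgroup label of the cell
#' @param cell_id optional integer id
#' @param meta optional list of extra metadata
#' @return object of class `morph_tree`
#' @export
morph_tree <- function(xyz, parent, diameter = NULL, layer = NULL,
                       subgroup = NA_character_, cell_id = NA_integer_,
                       meta = list()) {
  xyz <- as_xyz(xyz)
  n <- nrow(xyz)
  parent <- as.integer(parent)
  if (length(parent) != n) stop("parent length must match node count")
  if (sum(parent == 0L) != 1L) stop("tree must have exactly one root")
  if (parent[1] != 0L) stop("root must be the first node")
  if (any(parent[-1] >= seq_len(n)[-1]) || any(parent[-1] < 1L))
    stop("nodes must be in topological order (parent index < node index)")
  if (is.null(diameter)) diameter <- rep(1, n)
  if (any(diameter <= 0)) stop("diameters must be positive")
  structure(list(xyz = xyz, parent = parent,
                 diameter = rep_len(as.numeric(diameter), n),
                 layer = if (is.null(layer)) rep(NA_character_, n)
                         else rep_len(as.character(layer), n),
                 subgroup = subgroup, cell_id = cell_id, meta = meta),
            class = "morph_tree")
}

#' @export
print.morph_tree <- function(x, ...) {
  bs <- branch_stats(x)
  cat(sprintf(
    "morph_tree: %d nodes, %d stems, %d branch points, %d tips, %.0f um cable\n",
    nrow(x$xyz), bs$n_stems, bs$n_branch_points, bs$n_tips, bs$total_length))
  invisible(x)
}

#' Number of children of each node
#' @param tree a `morph_tree`
#' @return integer vector
#' @export
n_children <- function(tree) {
  tabulate(tree$parent, nbins = nrow(tree$xyz))
}

#' Edge lengths (um) from each node to its parent (0 for the root)
#' @param tree a `morph_tree`
#' @export
edge_lengths <- function(tree) {
  n <- nrow(tree$xyz)
  el <- numeric(n)
  if (n > 1) {
    i <- 2:n
    el[i] <- sqrt(rowSums((tree$xyz[i, , drop = FALSE] -
                           tree$xyz[tree$parent[i], , drop = FALSE])^2))
  }
  el
}

#' Path distance (um) from the root to each node
#' @param tree a `morph_tree`
#' @export
path_dists <- function(tree) {
  el <- edge_lengths(tree)
  pd <- numeric(length(el))
  for (i in seq_along(el)[-1]) pd[i] <- pd[tree$parent[i]] + el[i]
  pd
}

#' Total cable length of the tree (um)
#' @param tree a `morph_tree`
#' @export
total_length <- function(tree) sum(edge_lengths(tree))

# topological role of each node: root / tip / continuation / branch
node_roles <- function(tree) {
  nc <- n_children(tree)
  role <- ifelse(nc == 0L, "tip", ifelse(nc == 1L, "continuation", "branch"))
  role[1] <- "root"
  role
}

#' Decompose a tree into branches
#'
#' A branch is a path between consecutive topological points (root, branch
#' points, tips).  Returned as a list of node-index vectors ordered
#' proximal to distal; the first element of each vector is the parent
#' topological point.
#'
#' @param tree a `morph_tree`
#' @export
tree_branches <- function(tree) {
  role <- node_roles(tree)
  topo <- which(role %in% c("tip", "branch"))
  lapply(topo, function(t) {
    path <- t
    i <- tree$parent[t]
    while (i != 0L && role[i] == "continuation") {
      path <- c(i, path)
      i <- tree$parent[i]
    }
    c(i, path)
  })
}

#' Number of tips in the subtree rooted at each node
#' @param tree a `morph_tree`
#' @export
subtree_tips <- function(tree) {
  n <- nrow(tree$xyz)
  tips <- as.integer(n_children(tree) == 0L)
  for (i in n:2) tips[tree$parent[i]] <- tips[tree$parent[i]] + tips[i]
  tips
}
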