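# Shared expensive artifacts, built lazily once per test run.

.shared <- new.env(parent = emptyenv())

shared_volume <- function() {
  if (is.null(.shared$vol)) .shared$vol <- build_dg_volume()
  .shared$vol
}

shared_somata <- function() {
  if (is.null(.shared$somata))
    .shared$somata <- assign_subgroups(pack_somata(shared_volume(), seed = 1),
                                       shared_volume())
  .shared$somata
}

shared_oml_cloud <- function() {
  if (is.null(.shared$oml))
    .shared$oml <- boundary_cloud(shared_volume(), L = 3, n = 2e5, seed = 1)
  .shared$oml
}

# the scaled-down acceptance population: 200 cells sampled across the
# whole packed GCL with a fixed master seed
shared_population <- function() {
  if (is.null(.shared$pop)) {
    s <- shared_somata()
    set.seed(1)
    ids <- sort(sample(nrow(s), 200))
    .shared$pop <- generate_population(shared_volume(), s, cell_ids = ids,
                                       master_seed = 1)
  }
  .shared$pop
}

# independent Prim's MST total length via igraph, for wiring oracles
igraph_mst_length <- function(pts) {
  d <- as.matrix(dist(pts))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# exhaustive minimum spanning tree length by Prufer-sequence enumeration
# (all n^(n-2) labeled trees); feasible for n <= 8
exhaustive_mst_length <- function(pts) {
  n <- nrow(pts)
  stopifnot(n <= 8)
  d <- as.matrix(dist(pts))
  if (n == 2) return(d[1, 2])
  prufer_to_edges <- function(seq) {
    n <- length(seq) + 2L
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 1L
    for (i in seq_along(seq)) {
      leaf <- which(degree == 1L)[1]
      edges[ptr, ] <- c(leaf, seq[i]); ptr <- ptr + 1L
      degree[leaf] <- 0L
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    edges[ptr, ] <- which(degree == 1L)
    edges
  }
  best <- Inf
  idx <- rep(1L, n - 2)
  repeat {
    e <- prufer_to_edges(idx)
    len <- sum(d[e])
    if (len < best) best <- len
    j <- 1L
    while (j <= n - 2 && idx[j] == n) { idx[j] <- 1L; j <- j + 1L }
    if (j > n - 2) break
    idx[j] <- idx[j] + 1L
  }
  best
}
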