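# SWC morphology import/export and run configuration.

#' Write a tree to an SWC file
#'
#' Standard 7-column SWC: index, type (1 soma, 3 dendrite), x, y, z,
#' radius, parent (-1 for the root); indices are 1-based and radii are
#' half the stored diameters.
#'
#' @param tree a `morph_tree`
#' @param path output file path
#' @export
write_swc <- function(tree, path) {
  n <- nrow(tree$xyz)
  type <- c(1L, rep(3L, n - 1))
  parent <- ifelse(tree$parent == 0L, -1L, tree$parent)
  df <- data.frame(seq_len(n), type,
                   formatC(tree$xyz[, 1], format = "f", digits = 4),
                   formatC(tree$xyz[, 2], format = "f", digits = 4),
                   formatC(tree$xyz[, 3], format = "f", digits = 4),
                   formatC(tree$diameter / 2, format = "f", digits = 4),
                   parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC morphology written by dgforest",
               sprintf("# cell_id %s subgroup %s",
                       tree$cell_id, tree$subgroup)), con)
  write.table(df, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SWC morphology file
#'
#' Tolerant of comment headers, blank lines and whitespace dialects;
#' accepts forward-referenced parents (two-pass index resolution) and
#' rejects cyclic or dangling parent links.
#'
#' @param path SWC file path
#' @return a `morph_tree`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no data lines in SWC file")
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(fields, length, integer(1)) != 7
  if (any(bad)) stop("malformed SWC line(s): ", which(bad)[1])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  ids <- as.integer(m[, 1])
  parents <- as.integer(m[, 7])
  if (anyDuplicated(ids)) stop("duplicate SWC sample ids")
  idx <- match(parents, ids)            # two-pass: forward refs allowed
  root <- which(parents == -1L)
  if (length(root) != 1L) stop("SWC file must have exactly one root")
  if (any(is.na(idx[-root]))) stop("SWC parent id not present in file")
  # topological order by walking from the root; detects cycles
  children <- split(seq_along(ids), idx[seq_along(ids)])
  order <- integer(0)
  stack <- root
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, i)
    kids <- children[[as.character(i)]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  if (length(order) != length(ids))
    stop("cyclic or disconnected parent links in SWC file")
  pos <- match(seq_along(ids), order)
  new_parent <- ifelse(parents[order] == -1L, 0L, pos[idx[order]])
  morph_tree(m[order, 3:5, drop = FALSE], new_parent,
             diameter = 2 * m[order, 6])
}

#' Run configuration
#'
#' Bundles everything needed to reproduce a run: master seed, volume
#' parameters, the subgroup growth table, and the population selection.
#' Serializable to YAML via [write_run_config()].
#'
#' @param master_seed integer master seed
#' @param volume_params a `dg_surface_params` list
#' @param subgroup_params subgroup table
#' @param n_cells cells to grow (sampled evenly from the packed somata);
#'   `NULL` grows every packed soma
#' @param slice_u,slice_thickness optional region restriction: only grow
#'   cells within the transverse slab at angle `slice_u`
#' @param soma_subsample divisor applied to the packed-somata lattice for
#'   scaled-down runs (1 = full packing)
#' @export
run_config <- function(master_seed = 1, volume_params = dg_surface_params(),
                       subgroup_params = default_subgroup_params(),
                       n_cells = 200, slice_u = NULL, slice_thickness = 200,
                       soma_subsample = 1) {
  structure(list(master_seed = master_seed, volume_params = volume_params,
                 subgroup_params = subgroup_params, n_cells = n_cells,
                 slice_u = slice_u, slice_thickness = slice_thickness,
                 soma_subsample = soma_subsample),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  y <- config
  y$volume_params <- unclass(y$volume_params)
  y$subgroup_params <- lapply(seq_len(nrow(config$subgroup_params)),
                              function(i) as.list(config$subgroup_params[i, ]))
  yaml::write_yaml(unclass(y), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  vp <- do.call(dg_surface_params,
                y$volume_params[intersect(names(y$volume_params),
                                          names(formals(dg_surface_params)))])
  sp <- do.call(rbind, lapply(y$subgroup_params, as.data.frame))
  rownames(sp) <- sp$subgroup
  run_config(master_seed = y$master_seed, volume_params = vp,
             subgroup_params = sp, n_cells = y$n_cells,
             slice_u = y$slice_u, slice_thickness = y$slice_thickness,
             soma_subsample = y$soma_subsample)
}

#' Run the full generation pipeline
#'
#' Volume construction, soma packing (optionally lattice-subsampled),
#' subgroup labeling, region restriction, population growth, SWC export
#' and a morphometric report.
#'
#' @param config a `run_config`
#' @param out_dir output directory (`NULL` skips file export)
#' @param progress progress reporting interval (cells)
#' @return list with `volume`, `somata`, `trees`, `summary`, and stage
#'   timing in seconds.
#' @export
run_pipeline <- function(config, out_dir = NULL, progress = 0) {
  t0 <- proc.time()[3]
  volume <- build_dg_volume(config$volume_params)
  somata <- pack_somata(volume, seed = config$master_seed)
  somata <- assign_subgroups(somata, volume)
  if (!is.null(config$slice_u)) {
    pred <- transverse_slice(volume, config$slice_u, config$slice_thickness)
    somata <- somata[pred(as_xyz(somata[, c("x", "y", "z")])), ]
  }
  t1 <- proc.time()[3]
  ids <- seq_len(nrow(somata))
  if (!is.null(config$n_cells) && config$n_cells < length(ids)) {
    set.seed(config$master_seed)
    ids <- sort(sample(ids, config$n_cells))
  }
  trees <- generate_population(volume, somata, cell_ids = ids,
                               master_seed = config$master_seed,
                               tab = config$subgroup_params,
                               progress = progress)
  t2 <- proc.time()[3]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(somata, file.path(out_dir, "somata.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    for (tr in trees)
      write_swc(tr, file.path(out_dir, sprintf("cell_%06d.swc", tr$cell_id)))
  }
  summ <- population_summary(trees, volume)
  t3 <- proc.time()[3]
  if (!is.null(out_dir)) {
    write.table(cbind(measure = rownames(summ$overall), summ$overall),
                file.path(out_dir, "summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(volume = volume, somata = somata, trees = trees, summary = summ,
       timings = c(pack = t1 - t0, grow = t2 - t1, analyze = t3 - t2,
                   per_cell = (t2 - t1) / max(1, length(trees))))
}

#' Export an occupancy grid as columnar text
#' @param grid an `occupancy_grid`
#' @param path output path
#' @export
write_grid <- function(grid, path) {
  write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
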