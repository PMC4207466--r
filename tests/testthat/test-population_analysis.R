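# Voxel occupancy grids, correlations, layer profiles and simulated axon
# complexity on small constructed inputs.

test_that("occupancy grid bins segments into the right cubes", {
  box <- make_toy_volume("box", dims = c(400, 400, 400), layer = "IML")
  # one straight cable along +x at y = z = 5, from x = -90 to x = 90,
  # resampled at 5 um: segment midpoints fall in cubes k = floor(x/25)
  xyz <- cbind(seq(-90, 90, by = 5), 5, 5)
  tr <- morph_tree(xyz, c(0L, seq_len(nrow(xyz) - 1)), diameter = 1,
                   cell_id = 1L)
  g <- build_grid(list(tr), box, edge = 25, layers = "IML", min_cells = 1)
  expect_s3_class(g, "occupancy_grid")
  expect_equal(sum(g$length_um), 180, tolerance = 1e-9)
  expect_true(all(g$j == 0 & g$k == 0))
  expect_setequal(g$i, floor(seq(-87.5, 87.5, by = 5) / 25))
  # a fully traversed interior cube holds 25 um of cable
  full <- g[g$i == 0, ]
  expect_equal(full$length_um, 25, tolerance = 1e-9)
  expect_equal(full$density, 25 / 25^3, tolerance = 1e-12)
  expect_equal(full$occupancy_pct, 100 * pi * 0.5^2 * 25 / 25^3,
               tolerance = 1e-9)
  expect_true(all(g$n_cells == 1L))
})

test_that("unique cell counts accumulate across overlapping trees", {
  box <- make_toy_volume("box", dims = c(200, 200, 200), layer = "IML")
  mk <- function(id, y) {
    xyz <- cbind(seq(-20, 20, by = 5), y, 0)
    morph_tree(xyz, c(0L, seq_len(nrow(xyz) - 1)), cell_id = id)
  }
  g <- build_grid(list(mk(1L, 2), mk(2L, 4), mk(1L, 6)), box, edge = 25,
                  layers = "IML")
  expect_true(all(g$n_cells == 2L))   # two unique cells despite 3 trees
})

test_that("occupancy correlations are computed and bounded", {
  box <- make_toy_volume("box", dims = c(400, 400, 400), layer = "IML")
  set.seed(77)
  trees <- lapply(1:8, function(id) {
    n <- 60
    xyz <- rbind(c(0, 0, 0),
                 matrix(cumsum(rnorm(3 * n, 0, 4)), ncol = 3))
    xyz <- pmin(pmax(xyz, -180), 180)
    morph_tree(xyz, c(0L, seq_len(n)), cell_id = id)
  })
  g <- build_grid(trees, box, edge = 25, layers = "IML")
  cc <- occupancy_correlations(g)
  expect_named(cc, c("count_density", "count_occupancy",
                     "density_occupancy"))
  expect_true(all(abs(cc) <= 1))
  expect_gt(cc["density_occupancy"], 0)   # same cable drives both
})

test_that("layer profile reports per-layer means", {
  sh <- make_toy_volume("shell", dims = c(300, 60, 150))
  r <- seq(302, 448, by = 4)
  xyz <- cbind(r, 0.5, 0.5)
  tr <- morph_tree(xyz, c(0L, seq_len(length(r) - 1)), cell_id = 1L)
  g <- build_grid(list(tr), sh, edge = 25)
  lp <- layer_profile(g)
  expect_setequal(lp$layer, c("IML", "MML", "OML"))
  expect_true(all(lp$n_cubes >= 1))
  expect_true(all(lp$mean_density > 0))
})

test_that("axon complexity finds a low-branching solution for one cell", {
  center <- c(0, 0, 0)
  xyz <- cbind(seq(-12, 12, by = 2), 0, 0)
  tr <- morph_tree(xyz, c(0L, seq_len(nrow(xyz) - 1)), cell_id = 1L)
  ax <- axon_complexity(center, list(tr), edge = 25, reach = 30,
                        n_repeats = 3, increment = 3, seed = 2)
  # reach covers the whole cube: the very first axon already contacts
  expect_true(all(ax$n_points <= 3))
  expect_gte(ax$mean_branch_points, 0)
  # more cells spread apart require a more complex axon
  tr2 <- morph_tree(cbind(10, seq(-12, 12, by = 2), 0),
                    c(0L, seq_len(12)), cell_id = 2L)
  tr3 <- morph_tree(cbind(-10, seq(-12, 12, by = 2), 10),
                    c(0L, seq_len(12)), cell_id = 3L)
  ax3 <- axon_complexity(center, list(tr, tr2, tr3), edge = 25, reach = 2,
                         n_repeats = 3, increment = 5, seed = 2)
  expect_gte(ax3$mean_branch_points, 0)
  expect_true(all(ax3$n_points >= 5))
})

test_that("surface map assigns every cell to a face", {
  vol <- shared_volume()
  s <- shared_somata()
  oml <- shared_oml_cloud()
  set.seed(5)
  ids <- sample(nrow(s), 6)
  trees <- lapply(ids, function(i)
    generate_cell(vol, s[i, ], cell_id = i, master_seed = 2,
                  oml_cloud = oml))
  sm <- surface_map(trees, vol, statistic = "total_length", n_faces = 500)
  expect_true(all(c("face", "depth", "mean_value", "n") %in% names(sm)))
  expect_equal(sum(sm$n), 6)
  expect_true(all(sm$mean_value > 0))
  expect_false(is.null(attr(sm, "mesh")))
})
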