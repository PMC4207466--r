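# Wiring oracles and growth post-processing.

test_that("bf = 0 growth equals Prim's MST (igraph oracle), any reach", {
  set.seed(41)
  pts <- matrix(runif(60 * 3, 0, 200), ncol = 3)
  root <- c(100, 100, -10)
  all_pts <- rbind(root, pts)
  oracle <- igraph_mst_length(all_pts)
  for (mr in c(Inf, 50, 20, 5)) {
    tr <- grow_tree(root, pts, bf = 0, max_reach = mr)
    expect_equal(total_length(tr), oracle, tolerance = 1e-12,
                 label = paste("max_reach", mr))
  }
})

test_that("bf = 0 growth equals Prim's MST on a large point set", {
  set.seed(42)
  pts <- matrix(runif(500 * 3, 0, 400), ncol = 3)
  root <- c(200, 200, -20)
  tr <- grow_tree(root, pts, bf = 0)
  expect_equal(total_length(tr), igraph_mst_length(rbind(root, pts)),
               tolerance = 1e-12)
})

test_that("bf = 0 growth equals the exhaustive spanning-tree minimum", {
  for (rep in 1:5) {
    set.seed(50 + rep)
    n <- sample(4:7, 1)
    pts <- matrix(runif(n * 3, 0, 100), ncol = 3)
    root <- c(50, 50, -5)
    tr <- grow_tree(root, pts, bf = 0)
    expect_equal(total_length(tr), exhaustive_mst_length(rbind(root, pts)),
                 tolerance = 1e-12)
  }
})

test_that("collinear targets: chain below bf = 1, star collapse above", {
  pts <- cbind(0, 0, c(10, 25, 40, 60, 85))
  root <- c(0, 0, 0)
  # for bf < 1 extending the chain is always cheaper than re-attaching to
  # the root: ||t - tip|| + bf * pl(tip) < ||t - root|| exactly when bf < 1
  # on a collinear set with the root at one end
  for (bf in c(0, 0.5)) {
    tr <- grow_tree(root, pts, bf = bf)
    expect_equal(total_length(tr), 85)
    expect_equal(branch_stats(tr)$n_tips, 1L)
    expect_equal(branch_stats(tr)$n_branch_points, 0L)
  }
  # for bf > 1 the same inequality flips and the literal rule (unlimited
  # reach) yields the star: every target attaches to the root directly,
  # total length = sum of root distances
  for (bf in c(1.35, 5)) {
    tr <- grow_tree(root, pts, bf = bf)
    expect_equal(total_length(tr), sum(c(10, 25, 40, 60, 85)))
    expect_equal(branch_stats(tr)$n_tips, 5L)
    expect_equal(branch_stats(tr)$n_stems, 5L)
  }
})

test_that("total length rises and tip paths shrink with the balancing factor", {
  set.seed(60)
  pts <- matrix(runif(80 * 3, 0, 150), ncol = 3)
  root <- c(75, 75, -10)
  res <- t(vapply(c(0, 0.3, 0.6, 1.0, 1.5), function(bf) {
    tr <- grow_tree(root, pts, bf = bf)
    bs <- branch_stats(tr)
    c(len = bs$total_length, p2t = bs$mean_path_to_tips)
  }, numeric(2)))
  expect_true(all(diff(res[, "len"]) >= -1e-9))
  expect_true(all(diff(res[, "p2t"]) <= 1e-9))
})

test_that("forced stems set the root degree", {
  set.seed(61)
  pts <- matrix(runif(40 * 3, -80, 80), ncol = 3)
  root <- c(0, 0, -120)
  for (ns in 1:4) {
    stems <- init_stems(root, pts, ns)
    tr <- grow_tree(root, pts, bf = 1.0, stems = stems, max_reach = 60)
    expect_equal(branch_stats(tr)$n_stems, ns)
  }
})

test_that("trees contain every target exactly once", {
  set.seed(62)
  pts <- matrix(runif(30 * 3, 0, 100), ncol = 3)
  tr <- grow_tree(c(50, 50, -10), pts, bf = 0.9, max_reach = 50)
  expect_equal(nrow(tr$xyz), 31)
  # every target appears among the nodes
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9))
  expect_setequal(key(pts), key(tr$xyz[-1, , drop = FALSE]))
})

test_that("resampling preserves length, topology and endpoints", {
  set.seed(63)
  pts <- matrix(runif(40 * 3, 0, 120), ncol = 3)
  tr <- grow_tree(c(60, 60, -10), pts, bf = 0.5, max_reach = 60)
  bs0 <- branch_stats(tr)
  rs <- resample_tree(tr, spacing = 5)
  bs1 <- branch_stats(rs)
  # resampled points lie on the polyline, but chords between them cut
  # corners at original vertices, so length can only shrink, slightly
  expect_lte(bs1$total_length, bs0$total_length + 1e-9)
  expect_equal(bs1$total_length, bs0$total_length, tolerance = 0.01)
  expect_equal(bs1$n_tips, bs0$n_tips)
  expect_equal(bs1$n_branch_points, bs0$n_branch_points)
  expect_equal(bs1$n_stems, bs0$n_stems)
  expect_equal(bs1$max_order, bs0$max_order)
  # internal spacing close to the requested interval
  el <- edge_lengths(rs)[-1]
  expect_lt(max(el), 5 * 1.51)
  # root unchanged
  expect_equal(rs$xyz[1, ], tr$xyz[1, ])
})

test_that("jitter preserves the root and topology; zero amplitude is identity", {
  set.seed(64)
  pts <- matrix(runif(25 * 3, 0, 100), ncol = 3)
  tr <- resample_tree(grow_tree(c(50, 50, -10), pts, bf = 0.5,
                                max_reach = 60), 5)
  j0 <- apply_jitter(tr, amplitudes = c(0, 0))
  expect_identical(j0$xyz, tr$xyz)
  set.seed(1)
  j <- apply_jitter(tr, amplitudes = c(2.5, 7))
  expect_equal(j$xyz[1, ], tr$xyz[1, ])
  expect_identical(j$parent, tr$parent)
  expect_gt(total_length(j), total_length(tr))
})

test_that("diameter taper is monotone in path distance away from the soma", {
  set.seed(65)
  pts <- matrix(runif(30 * 3, 0, 120), ncol = 3)
  tr <- resample_tree(grow_tree(c(60, 60, -10), pts, bf = 0.5,
                                max_reach = 60), 5)
  tp <- apply_taper(tr, d_max = 2.2, d_tip = 0.75, lambda = 5,
                    soma_diameter = 12.54)
  expect_equal(tp$diameter[1], 12.54)
  x <- path_dists(tp)
  far <- x > 15   # beyond the near-soma ramp
  d <- tp$diameter
  # per-edge monotonicity in the taper region
  idx <- which(seq_along(x) > 1)          # skip the root (parent id 0)
  i <- idx[far[idx] & far[tp$parent[idx]]]
  expect_true(all(d[i] <= d[tp$parent[i]] + 1e-9))
  expect_true(all(d[-1] >= 0.3))
})

test_that("cell generation is deterministic in (cell id, master seed)", {
  vol <- shared_volume()
  s <- shared_somata()
  oml <- shared_oml_cloud()
  t1 <- generate_cell(vol, s[500, ], cell_id = 500, master_seed = 9,
                      oml_cloud = oml)
  t2 <- generate_cell(vol, s[500, ], cell_id = 500, master_seed = 9,
                      oml_cloud = oml)
  expect_identical(t1$xyz, t2$xyz)
  expect_identical(t1$parent, t2$parent)
  expect_identical(t1$diameter, t2$diameter)
  t3 <- generate_cell(vol, s[500, ], cell_id = 500, master_seed = 10,
                      oml_cloud = oml)
  expect_false(identical(t1$xyz, t3$xyz))
})

test_that("generated cells are anatomically plausible", {
  vol <- shared_volume()
  s <- shared_somata()
  oml <- shared_oml_cloud()
  set.seed(8)
  for (i in sample(nrow(s), 4)) {
    tr <- generate_cell(vol, s[i, ], cell_id = i, master_seed = 3,
                        oml_cloud = oml)
    bs <- branch_stats(tr)
    expect_gte(bs$n_stems, 1)
    expect_lte(bs$n_stems, 4)
    expect_gt(bs$total_length, 500)
    expect_lt(bs$total_length, 10000)
    lab <- classify_points(vol, tr$xyz)
    expect_lt(mean(lab == "OUTSIDE"), 0.05)   # jitter may nick the shell
    expect_identical(tr$subgroup, s$subgroup[i])
  }
})
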