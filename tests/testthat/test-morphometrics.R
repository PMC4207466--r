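# Morphometric unit oracles: fixture trees with hand-computable
# statistics, plus closed-form checks of Sholl, contraction, asymmetry
# and laminar attribution.

test_that("straight cable fixture matches closed forms", {
  fx <- make_fixture_tree("straight", seg = 20)
  bs <- branch_stats(fx$tree)
  expect_equal(bs$total_length, fx$expected$total_length)
  expect_equal(bs$n_tips, fx$expected$n_tips)
  expect_equal(bs$n_branch_points, fx$expected$n_branch_points)
  expect_equal(bs$n_branches, fx$expected$n_branches)
  expect_equal(bs$max_order, fx$expected$max_order)
  expect_true(is.na(asymmetry(fx$tree)))
  expect_equal(unname(contraction(fx$tree)), 1)
})

test_that("y fixture matches closed forms", {
  fx <- make_fixture_tree("y")
  bs <- branch_stats(fx$tree)
  expect_equal(bs$total_length, fx$expected$total_length)
  expect_equal(bs$n_branch_points, 1L)
  expect_equal(bs$n_branches, 3L)
  expect_equal(bs$max_order, 1L)
  # single (1,1) cherry: partition asymmetry is undefined
  expect_true(is.na(asymmetry(fx$tree)))
})

test_that("full binary fixture: perfectly balanced tree scores zero", {
  for (depth in 3:4) {
    fx <- make_fixture_tree("binary", depth = depth)
    bs <- branch_stats(fx$tree)
    expect_equal(bs$n_tips, 2^depth)
    expect_equal(bs$n_branch_points, 2^depth - 2)
    expect_equal(bs$n_branches, 2 * 2^depth - 2)
    expect_equal(bs$max_order, depth - 1)
    expect_equal(asymmetry(fx$tree), 0)
  }
})

test_that("comb (caterpillar) fixture scores one at any size", {
  for (tips in c(4, 8, 13)) {
    fx <- make_fixture_tree("comb", tips = tips)
    bs <- branch_stats(fx$tree)
    expect_equal(bs$n_tips, tips)
    expect_equal(bs$n_branch_points, tips - 1)
    expect_equal(asymmetry(fx$tree), 1)
  }
})

test_that("granule-cell-like fixture matches its hand counts", {
  fx <- make_fixture_tree("gclike")
  bs <- branch_stats(fx$tree)
  expect_equal(bs$n_tips, fx$expected$n_tips)
  expect_equal(bs$n_branch_points, fx$expected$n_branch_points)
  expect_equal(bs$n_stems, fx$expected$n_stems)
  expect_equal(bs$n_branches, fx$expected$n_branches)
  expect_equal(bs$max_order, fx$expected$max_order)
})

test_that("asymmetry handles mixed partitions by exclusion", {
  # root - bp A with daughters: (tip) and (bp B with 2 tips):
  # A partitions (1, 2) -> |1-2|/(3-2) = 1; B is a (1,1) cherry, excluded
  xyz <- rbind(c(0, 0, 0), c(0, 0, 10), c(10, 0, 20), c(-10, 0, 20),
               c(-15, 0, 30), c(-5, 0, 30))
  tr <- morph_tree(xyz, c(0L, 1L, 2L, 2L, 4L, 4L))
  expect_equal(asymmetry(tr), 1)
  # depth-2 binary tree: every branch point is a (1,1) cherry -> NA
  fx <- make_fixture_tree("binary", depth = 2)
  expect_true(is.na(asymmetry(fx$tree)))
})

test_that("Sholl crossings match hand counts on simple trees", {
  fx <- make_fixture_tree("straight", seg = 20)   # 100 um straight cable
  sh <- sholl(fx$tree, radii = c(10, 50, 99.5, 150))
  expect_equal(sh$crossings, c(1L, 1L, 1L, 0L))
  fy <- make_fixture_tree("y")$tree   # bifurcation 40 um up, tips at ~90
  sh2 <- sholl(fy, radii = c(20, 60, 200))
  expect_equal(sh2$crossings, c(1L, 2L, 0L))
})

test_that("contraction is the ratio of Euclidean to path length", {
  # two-node dog-leg: branch from (0,0,0) to (30,40,0) via (30,0,0)
  xyz <- rbind(c(0, 0, 0), c(30, 0, 0), c(30, 40, 0))
  tr <- morph_tree(xyz, c(0L, 1L, 2L))
  expect_equal(unname(contraction(tr)), 50 / 70)
})

test_that("laminar distribution attributes segments by midpoint layer", {
  # shell volume: GCL [240,300), IML [300,350), MML [350,400), OML [400,450]
  sh <- make_toy_volume("shell", dims = c(300, 60, 150))
  # radial cable along +x from r=280 to r=440 in 20 um steps
  r <- seq(280, 440, by = 20)
  xyz <- cbind(r, 0, 0)
  tr <- morph_tree(xyz, c(0L, seq_len(length(r) - 1)))
  ld <- laminar_distribution(tr, sh)
  # segment midpoints: 290 (GCL->IML), 310, 330, 350(MML), 370, 390,
  # 410(OML), 430 -- each segment 20 um
  expect_equal(ld["IML", "pct_length"], 100 * 3 / 8)
  expect_equal(ld["MML", "pct_length"], 100 * 3 / 8)
  expect_equal(ld["OML", "pct_length"], 100 * 2 / 8)
  # no branch points at all: percentages all zero
  expect_true(all(ld$pct_branch_points == 0))
})

test_that("laminar branch points fold GCL into IML", {
  sh <- make_toy_volume("shell", dims = c(300, 60, 150))
  # branch point at r=290 (inside GCL) and one at r=370 (MML)
  xyz <- rbind(c(280, 0, 0), c(290, 0, 0), c(295, 5, 0), c(295, -5, 0),
               c(370, 0, 0), c(380, 5, 0), c(380, -5, 0))
  tr <- morph_tree(xyz, c(0L, 1L, 2L, 2L, 3L, 5L, 5L))
  ld <- laminar_distribution(tr, sh)
  expect_equal(ld["IML", "pct_branch_points"], 50)
  expect_equal(ld["MML", "pct_branch_points"], 50)
  expect_equal(ld["OML", "pct_branch_points"], 0)
})

test_that("spreads measure tip extents along supplied axes", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 50), c(40, 0, 80), c(-25, 0, 80),
               c(0, 12, 80))
  tr <- morph_tree(xyz, c(0L, 1L, 2L, 2L, 2L))
  sp <- spreads(tr, frame = "cone",
                axes = list(t_hat = c(1, 0, 0), l_hat = c(0, 1, 0),
                            axis = c(0, 0, 1)))
  expect_equal(unname(sp["transverse"]), 65)
  expect_equal(unname(sp["longitudinal"]), 12)
})

test_that("population summary aggregates and contrasts subgroups", {
  set.seed(12)
  trees <- list()
  for (i in 1:6) {
    fx <- make_fixture_tree("binary", depth = 3)$tree
    fx$subgroup <- if (i <= 3) "supra_deep" else "infra_deep"
    fx$cell_id <- i
    fx$xyz <- fx$xyz + rnorm(length(fx$xyz), 0, 0.01)
    trees[[i]] <- fx
  }
  ps <- population_summary(trees)
  expect_equal(nrow(ps$cells), 6)
  expect_true("total_length" %in% rownames(ps$overall))
  expect_true(all(c("supra_deep", "infra_deep") %in% names(ps$by_subgroup)))
  expect_true(is.data.frame(ps$tests))
})

test_that("standard-error conversion supports both conventions", {
  expect_equal(sd_from_se(2, 25), 10)
  expect_equal(sd_from_se(2, 25, exact_text = TRUE), 50)
})
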