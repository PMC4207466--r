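# Target points: cone membership closed form, sampling distribution,
# cone orientation, laminar quotas, truncated-Poisson stem sampler.

test_that("cone membership matches the closed-form inequality", {
  cone <- structure(list(apex = c(0, 0, 0), soma = c(0, 0, 0),
                         axis = c(0, 0, 1), t_hat = c(1, 0, 0),
                         l_hat = c(0, 1, 0), rt = 100, rl = 60, h = 300),
                    class = "elliptical_cone")
  set.seed(9)
  pts <- cbind(runif(2000, -150, 150), runif(2000, -100, 100),
               runif(2000, -50, 350))
  got <- cone_select(cone, pts)
  manual <- pts[, 3] >= 0 & pts[, 3] <= 300 &
    (pts[, 1] / 100)^2 + (pts[, 2] / 60)^2 <= (pts[, 3] / 300)^2 + 1e-12
  expect_identical(unname(got), unname(manual))
  # apex and base-center points
  expect_true(cone_select(cone, matrix(c(0, 0, 0), 1)))
  expect_true(cone_select(cone, matrix(c(0, 0, 300), 1)))
  expect_false(cone_select(cone, matrix(c(0, 0, 301), 1)))
  expect_false(cone_select(cone, matrix(c(99, 0, 10), 1)))
})

test_that("cone sampling is inside the cone and uniform in volume", {
  cone <- structure(list(apex = c(10, -20, 5), soma = c(10, -20, 5),
                         axis = c(0, 0, 1), t_hat = c(1, 0, 0),
                         l_hat = c(0, 1, 0), rt = 120, rl = 70, h = 400),
                    class = "elliptical_cone")
  set.seed(10)
  pts <- sample_in_cone(cone, 4000, z_exp = 3)
  expect_true(all(cone_select(cone, pts)))
  z <- pts[, 3] - 5
  # uniform in volume: E[z/h] = 3/4, and P(z <= h/2) = 1/8
  expect_equal(mean(z / 400), 0.75, tolerance = 0.01)
  expect_equal(mean(z <= 200), 1 / 8, tolerance = 0.25)
  # larger exponent biases the axial position distally
  set.seed(10)
  pts6 <- sample_in_cone(cone, 4000, z_exp = 6)
  expect_gt(mean(pts6[, 3]), mean(pts[, 3]))
})

test_that("oriented cones reach the outer boundary with a sane frame", {
  vol <- shared_volume()
  s <- shared_somata()
  oml <- shared_oml_cloud()
  set.seed(3)
  for (i in sample(nrow(s), 5)) {
    cone <- orient_cone(vol, s[i, ], oml, rt = 150, rl = 80)
    expect_s3_class(cone, "elliptical_cone")
    expect_equal(sum(cone$axis^2), 1, tolerance = 1e-9)
    expect_equal(sum(cone$t_hat^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(cone$axis * cone$t_hat)), 1e-9)
    expect_lt(abs(sum(cone$axis * cone$l_hat)), 1e-9)
    # the cone tip (height along axis) lies at/just past the OML shell
    tip <- cone$apex + cone$h * cone$axis
    d <- sqrt(min(colSums((t(oml) - tip)^2)))
    expect_lt(d, 30)
    # height is bounded by the anatomy (soma to outer shell distance)
    expect_gt(cone$h, 150)
    expect_lt(cone$h, 800)
  }
  expect_error(orient_cone(vol, s[1, ], oml, rt = 50, rl = 80),
               "transverse")
})

test_that("apex offset displaces the virtual apex but not the soma", {
  vol <- shared_volume()
  s <- shared_somata()
  oml <- shared_oml_cloud()
  c0 <- orient_cone(vol, s[10, ], oml, rt = 150, rl = 80)
  c40 <- orient_cone(vol, s[10, ], oml, rt = 150, rl = 80, apex_offset = 40)
  expect_equal(c40$soma, c0$soma)
  expect_equal(c40$apex, c0$apex - 40 * c0$axis)
  expect_equal(c40$h, c0$h + 40)
})

test_that("laminar quotas scale with the subgroup means", {
  tab <- default_subgroup_params()
  set.seed(20)
  q <- t(replicate(600, draw_quota("supra_superficial", tab)))
  expect_identical(colnames(q), c("GCL", "IML", "MML", "OML"))
  expect_true(all(q >= 0))
  row <- tab["supra_superficial", ]
  f <- c(row$f_gcl, row$f_iml, row$f_mml, row$f_oml)
  expect_equal(unname(colMeans(q)), row$n_nodes * f / sum(f),
               tolerance = 0.1)
})

test_that("truncated-Poisson sampler matches its pmf and mean", {
  lambda <- 2.643
  k <- 1:4
  pmf <- dpois(k, lambda) / sum(dpois(k, lambda))
  expect_equal(trunc_pois_mean(lambda), sum(k * pmf))
  set.seed(30)
  draws <- rtrunc_pois(20000, lambda)
  expect_true(all(draws %in% k))
  freq <- tabulate(draws, 4) / 20000
  expect_equal(freq, pmf, tolerance = 0.03)
  # lambda solver inverts the mean
  for (m in c(1.4, 1.5, 2.0, 2.4)) {
    expect_equal(trunc_pois_mean(trunc_pois_lambda(m)), m, tolerance = 1e-6)
  }
})

test_that("target selection honors the quota and stays in the cone", {
  vol <- shared_volume()
  s <- shared_somata()
  oml <- shared_oml_cloud()
  cone <- orient_cone(vol, s[100, ], oml, rt = 160, rl = 90,
                      apex_offset = 40)
  set.seed(4)
  quota <- c(GCL = 3, IML = 15, MML = 12, OML = 12)
  sel <- dgforest:::select_targets(vol, cone, quota)
  expect_lte(nrow(sel), sum(quota))
  expect_gte(nrow(sel), sum(quota) * 0.7)  # most layers attainable
  expect_true(all(cone_select(cone, sel)))
  lab <- classify_points(vol, sel)
  expect_true(all(lab != "OUTSIDE"))
  tab <- table(factor(lab, levels = names(quota)))
  expect_true(all(tab <= quota))
})
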