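test_that("a hand-built three-point cloud across four bins gives the hand-derived steps", {
  # points: (0.1, 5), (0.3, 8), (0.9, 2); m = 4 bins of width 0.25
  # sub_min: bin1 = 5, bin2 = 8, bin3 = empty -> max E = 8, bin4 = 2
  # e_min (suffix minima): bin1 = 2, bin2 = 2, bin3 = 2, bin4 = 2
  pts <- tibble::tibble(U_N = c(0.1, 0.3, 0.9), E = c(5, 8, 2))
  fr <- build_frontier(pts, m = 4)
  expect_equal(fr$sub_min, c(5, 8, 8, 2))
  expect_equal(fr$e_min, c(2, 2, 2, 2))

  # increasing cloud keeps its own mins: (0.1, 2), (0.3, 5), (0.9, 8)
  pts2 <- tibble::tibble(U_N = c(0.1, 0.3, 0.9), E = c(2, 5, 8))
  fr2 <- build_frontier(pts2, m = 4)
  expect_equal(fr2$sub_min, c(2, 5, 8, 8))
  expect_equal(fr2$e_min, c(2, 5, 8, 8))
})

test_that("all points in one bin produce a flat suffix up to that bin", {
  pts <- tibble::tibble(U_N = c(0.52, 0.55, 0.58), E = c(9, 4, 6))
  fr <- build_frontier(pts, m = 5)
  expect_equal(fr$e_min, c(4, 4, 4, 9, 9))
})

test_that("U_N = 1 lands in the last bin and every U_N lands in exactly one bin", {
  pts <- tibble::tibble(U_N = c(1, 0.4), E = c(3, 1))
  fr <- build_frontier(pts, m = 2)
  expect_equal(fr$sub_min, c(1, 3))
  # a value exactly on an interior bin edge belongs to the upper bin
  expect_identical(ecatradeoff:::frontier_bin(0.5, 2), 2L)
  u <- seq(0.001, 1, length.out = 97)
  bins <- ecatradeoff:::frontier_bin(u, 52)
  expect_true(all(bins >= 1 & bins <= 52))
  expect_true(all(u >= (bins - 1) / 52 & (u < bins / 52 | bins == 52)))
})

test_that("the frontier is a monotone non-decreasing step function below sub_min", {
  pts <- rule_metrics(0:255, n = 4, horizon = 3, cap = 16, t_theta = 10)
  fr <- build_frontier(pts, m = 13)
  expect_true(all(diff(fr$e_min) >= 0))
  expect_true(all(fr$e_min <= fr$sub_min))
  expect_error(build_frontier(pts[0, ], m = 13), "empty")
})

test_that("synchronous points never break their own frontier", {
  pts <- rule_metrics(0:255, n = 4, horizon = 3, cap = 16, t_theta = 10)
  fr <- build_frontier(pts, m = 13)
  br <- breaking_degree(fr, pts)
  expect_equal(br$D_B, 0)
  expect_identical(glance(br)$n_below, 0L)
})

test_that("one synthetic point strictly below its bin counts 1/256, invariant to order", {
  pts <- rule_metrics(0:255, n = 4, horizon = 3, cap = 16, t_theta = 10)
  fr <- build_frontier(pts, m = 13)
  fake <- pts
  k <- ecatradeoff:::frontier_bin(fake$U_N[10], 13)
  fake$E[10] <- fr$e_min[k] - 1e-9
  expect_equal(breaking_degree(fr, fake)$D_B, 1 / 256)
  shuffled <- fake[sample(nrow(fake)), ]
  expect_equal(breaking_degree(fr, shuffled)$D_B, 1 / 256)
})

test_that("mismatched parameterizations are refused", {
  a <- rule_metrics(0:15, n = 4, horizon = 3, cap = 16, t_theta = 10)
  b <- rule_metrics(0:15, n = 4, horizon = 2, cap = 16, t_theta = 10)
  fr <- build_frontier(a, m = 4)
  expect_error(breaking_degree(fr, b), "disagree")
})

test_that("tidy and glance expose the frontier table and parameters", {
  pts <- tibble::tibble(U_N = c(0.1, 0.9), E = c(5, 2))
  fr <- build_frontier(pts, m = 4)
  expect_identical(nrow(tidy(fr)), 4L)
  expect_identical(glance(fr)$m, 4L)
  expect_equal(glance(fr)$fill_value, 5)
})
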