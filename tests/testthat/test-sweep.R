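test_that("sweep endpoints give the degenerate single-segment counts", {
  sw <- sweep_segments(c(18, 90), p_grid = c(0, 0.5, 1), n_cells = 400,
                       seed = 1)
  at0 <- dplyr::filter(sw, p == 0)
  expect_true(all(at0$N1 == 1))
  expect_true(all(at0$N1_norm == 1 / 400))
  expect_true(all(at0$N2_norm == 1 / 256))
  at1 <- dplyr::filter(sw, p == 1)
  expect_true(all(at1$N1 == 1))
  expect_true(all(at1$ratio == 1))
})

test_that("sweep counts obey their structural invariants", {
  sw <- sweep_segments(c(18, 50, 90, 110), p_grid = seq(0, 0.9, 0.15),
                       n_cells = 500, seed = 3)
  expect_true(all(sw$N2 <= sw$N1))
  expect_true(all(sw$ratio >= 1))
  expect_true(all(sw$N1_norm >= 1 / 500 & sw$N1_norm <= 1))
  sm <- sweep_summary(sw)
  # averaged curves lie within the per-rule envelope pointwise
  env <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(sw), p),
                          lo = min(N1_norm), hi = max(N1_norm))
  expect_true(all(sm$N1_norm >= env$lo & sm$N1_norm <= env$hi))
})

test_that("a mid-range skip probability maximizes segment counts for rule 18", {
  sw <- sweep_segments(18, p_grid = c(0.05, 0.5, 0.95), n_cells = 4000,
                       seed = 5, replicates = 3)
  mid <- dplyr::filter(sw, p == 0.5)$N1
  expect_gt(mid, dplyr::filter(sw, p == 0.05)$N1)
  expect_gt(mid, dplyr::filter(sw, p == 0.95)$N1)
})

test_that("sweeps are reproducible and entry-wise independent of the grid shape", {
  a <- sweep_segments(18, p_grid = c(0.2, 0.6), n_cells = 300, seed = 9)
  b <- sweep_segments(18, p_grid = c(0.2, 0.6), n_cells = 300, seed = 9)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("polynomial fitting recovers exact generators and guards degenerates", {
  x <- seq(0, 1, 0.1)
  y <- 2 - 3 * x + 0.5 * x^2 + x^3 - 0.25 * x^4
  fit <- fit_polynomial(x, y, degree = 4)
  expect_equal(fit$coefficients, c(-0.25, 1, 0.5, -3, 2), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  # constant target: R^2 defined as 0, higher coefficients ~ 0
  cfit <- fit_polynomial(x, rep(2, length(x)), degree = 4)
  expect_equal(cfit$r_squared, 0)
  expect_equal(cfit$coefficients[1:4], rep(0, 4), tolerance = 1e-10)
  expect_error(fit_polynomial(c(1, 1, 1), c(1, 2, 3), degree = 2), "distinct")
  # OLS normal equations: residuals orthogonal to the design columns
  yn <- y + withr::with_seed(1, rnorm(length(y), sd = 0.1))
  fn <- fit_polynomial(x, yn, degree = 4)
  res <- stats::residuals(fn$fit)
  for (d in 0:4) expect_lt(abs(sum(res * x^d)), 1e-8)
})

test_that("tidy and glance expose polynomial fits broom-style", {
  fit <- fit_polynomial(seq(0, 1, 0.25), c(0, 1, 0, 1, 0), degree = 2)
  td <- tidy(fit)
  expect_identical(td$term, c("x^2", "x^1", "x^0"))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("ratio regression handles collinear and degenerate inputs", {
  sm <- tibble::tibble(p = seq(0.1, 0.5, 0.1), ratio = c(2, 4, 6, 8, 10))
  br <- tibble::tibble(p = sm$p, D_B = 0.05 * sm$ratio + 0.1)
  rv <- ratio_vs_breaking(sm, br, p_range = c(0.05, 0.55))
  expect_equal(rv$ratio$r_squared, 1)
  expect_equal(rv$ratio$coefficients, c(0.05, 0.1), tolerance = 1e-10)
  # constant D_B: nothing to explain
  br0 <- tibble::tibble(p = sm$p, D_B = rep(0.4, 5))
  rv0 <- ratio_vs_breaking(sm, br0, p_range = c(0.05, 0.55))
  expect_equal(rv0$ratio$r_squared, 0)
  # unspecified range warns; too few shared points errors
  expect_warning(ratio_vs_breaking(sm, br), "0.05")
  expect_error(ratio_vs_breaking(sm[1:2, ], br[1:2, ], p_range = c(0, 1)),
               "Fewer than 3")
})
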