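test_that("universality of the worked n = 2 cases is exact", {
  expect_identical(reachable_set(0, n = 2)$U, 1L)
  expect_identical(reachable_set(204, n = 2)$U, 4L)
  expect_equal(reachable_set(204, n = 2)$U_N, 1)
  # and via the tabular interface
  tab <- rule_metrics(c(0, 204), n = 2, horizon = 3, cap = 8, t_theta = 10)
  expect_equal(tab$U, c(1, 4))
})

test_that("reach times match the closed forms for frozen and collapsing rules", {
  # rule 204: only the row equal to X hits (at step 1); all others time out
  expect_equal(tau(204, state = "00000000", n = 8, t_theta = 70),
               1 + 70 * 255)
  expect_equal(efficiency(204, n = 8, t_theta = 70), 1 + 70 * 255)
  # rule 0: every row reaches the zero state at step 1
  for (n in c(3, 6, 8)) {
    expect_equal(tau(0, state = rep(0, n), n = n, t_theta = 70), 2^n)
    expect_equal(efficiency(0, n = n, t_theta = 70), 2^n)
  }
})

test_that("tau is undefined for non-reachable states", {
  # rule 0 reaches only the zero row
  expect_error(tau(0, state = "0001", n = 4), "not reachable")
})

test_that("exhaustive brute-force oracle reproduces reachability, tau and E at n <= 4", {
  for (rule in c(18, 90, 110, 150, 30, 0, 204)) {
    for (n in c(3, 4)) {
      orc <- oracle_metrics(rule, n, horizon = 3, cap = 2^n, t_theta = 9,
                            boundary_seed = 1L)
      rec <- reachable_set(rule, n = n, horizon = 3, boundary_seed = 1L)
      expect_identical(sort(rec$states), as.integer(orc$reachable))
      expect_equal(efficiency(rule, n = n, horizon = 3, cap = 2^n,
                              t_theta = 9, boundary_seed = 1L), orc$E)
      for (j in seq_along(orc$reachable)) {
        expect_equal(tau(rule, state = orc$reachable[j], n = n, horizon = 3,
                         cap = 2^n, t_theta = 9, boundary_seed = 1L),
                     orc$tau[j])
      }
    }
  }
})

test_that("rule 90 universality at n = 4, T = 3 equals the enumeration oracle", {
  orc <- oracle_metrics(90, 4, horizon = 3, cap = 16, t_theta = 70,
                        boundary_seed = 1L)
  expect_identical(reachable_set(90, n = 4, horizon = 3)$U, orc$U)
})

test_that("asynchronous metrics at p = 0 equal the synchronous record exactly", {
  sync <- rule_metrics(c(18, 90, 110), n = 5, horizon = 4, cap = 32,
                       t_theta = 20)
  asy <- rule_metrics(c(18, 90, 110), n = 5, horizon = 4, cap = 32,
                      t_theta = 20, p = 0, replicates = 1, seed = 42)
  expect_identical(sync$U, asy$U)
  expect_identical(sync$E, asy$E)
})

test_that("asynchronous metrics are reproducible under the master seed", {
  a <- rule_metrics(22, n = 5, horizon = 4, cap = 16, t_theta = 10, p = 0.3,
                    replicates = 10, seed = 7)
  b <- rule_metrics(22, n = 5, horizon = 4, cap = 16, t_theta = 10, p = 0.3,
                    replicates = 10, seed = 7)
  expect_identical(a, b)
  c <- rule_metrics(22, n = 5, horizon = 4, cap = 16, t_theta = 10, p = 0.3,
                    replicates = 10, seed = 8)
  expect_false(identical(a$E, c$E))
})

test_that("every rule's universality is at least that of rule 0", {
  tab <- rule_metrics(seq(0, 255, by = 17), n = 4, horizon = 3, cap = 16,
                      t_theta = 10)
  expect_true(all(tab$U_N >= 1 / 2^4))
  # tau lower bound: each of the 2^n rows contributes at least 1 step
  expect_true(all(tab$E >= 2^4))
})

test_that("oversized lattices are refused with guidance", {
  expect_error(rule_metrics(18, n = 13), "Reduce `n`")
  expect_error(reachable_set(18, n = 21), "Reduce `n`")
})

test_that("p = 1 asynchronous metrics equal the synchronous metrics of rule 204", {
  asy <- rule_metrics(c(18, 90), n = 5, horizon = 4, cap = 32, t_theta = 20,
                      p = 1, replicates = 1, seed = 1)
  sync204 <- rule_metrics(204, n = 5, horizon = 4, cap = 32, t_theta = 20)
  expect_equal(asy$U, rep(sync204$U, 2))
  expect_equal(asy$E, rep(sync204$E, 2))
})
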