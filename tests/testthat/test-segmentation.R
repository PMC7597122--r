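test_that("the worked transition prefix segments as derived by hand", {
  # before a_0..a_5 = 0,0,1,0,0,(1); after cells 1..4 = 1,0,1,0; base R18.
  # Cell 1 fixes d_1 = 1, cell 2 fixes d_2 = 0, cell 3 fixes d_4 = 1;
  # cell 4 observes d_1 = 0, conflicting, so segment 1 = cells 1..3 and its
  # completed rule is R18 itself (d_1 = d_4 = 1 determined, rest from base).
  seg <- segment_transition("0100", "1010", base = 18, boundary = c(0, 1))
  expect_identical(seg$segments$end[1], 3L)
  expect_identical(seg$segments$rule[1], 18L)
  expect_identical(seg$segments$start[2], 4L)
  expect_identical(seg$N1, 2L)
  det1 <- seg$segments$determined[[1]]
  expect_identical(unname(det1[c("d1", "d2", "d4")]), c(1L, 0L, 1L))
  expect_true(all(is.na(det1[c("d0", "d3", "d5", "d6", "d7")])))
  expect_true(verify_segmentation(seg))
})

test_that("a synchronous pair yields a single segment completed to the base rule", {
  withr::with_seed(3, {
    for (i in 1:20) {
      base <- sample(0:255, 1)
      cfg <- random_configuration(sample(5:40, 1))
      seg <- segment_transition(cfg, step_sync(cfg, base)$cells, base = base)
      expect_identical(seg$N1, 1L)
      expect_identical(seg$segments$rule, base)
    }
  })
})

test_that("a fully skipped transition over all 8 neighbourhoods reads as rule 204", {
  # a row long enough to contain every triplet; p = 1 keeps every cell
  cfg <- random_configuration(60, seed = 2)
  seg <- segment_transition(cfg, cfg$cells, base = 18)
  expect_identical(seg$N1, 1L)
  expect_identical(seg$segments$rule, 204L)
})

test_that("segmentation agrees with an independent greedy oracle on random pairs", {
  withr::with_seed(11, {
    for (i in 1:60) {
      n <- 30
      base <- sample(0:255, 1)
      before <- sample(0:1, n, replace = TRUE)
      after <- sample(0:1, n, replace = TRUE)  # arbitrary pair, not dynamics
      b <- sample(0:1, 2, replace = TRUE)
      seg <- segment_transition(before, after, base = base, boundary = b)
      orc <- oracle_segment(before, after, b[1], b[2], base)
      expect_identical(seg$segments$start, as.integer(orc$starts))
      expect_identical(seg$segments$rule, as.integer(orc$rules))
      expect_identical(seg$N1, orc$N1)
      expect_identical(seg$N2, orc$N2)
    }
  })
})

test_that("every segmentation reconstructs its transition (1000 random pairs)", {
  withr::with_seed(19, {
    for (i in 1:1000) {
      n <- sample(3:40, 1)
      base <- sample(0:255, 1)
      p <- runif(1)
      cfg <- random_configuration(n)
      after <- step_async(cfg, base, p)$cells
      seg <- segment_transition(cfg, after, base = base)
      expect_true(verify_segmentation(seg))
      expect_lte(seg$N2, seg$N1)
    }
  })
})

test_that("completed rules of async-generated pairs are apparent rules of the base", {
  withr::with_seed(23, {
    for (base in c(18, 90, 110, 30)) {
      ar <- apparent_rules(base)
      for (i in 1:25) {
        cfg <- random_configuration(50)
        after <- step_async(cfg, base, p = runif(1))$cells
        seg <- segment_transition(cfg, after, base = base)
        expect_true(all(seg$segments$rule %in% ar))
      }
    }
  })
})

test_that("degenerate regimes produce a single segment", {
  cfg <- random_configuration(30, seed = 4)
  for (p in c(0, 1)) {
    after <- step_async(cfg, 90, p = p, seed = 1)$cells
    expect_identical(segment_transition(cfg, after, base = 90)$N1, 1L)
  }
})

test_that("tampered rules fail verification", {
  cfg <- random_configuration(30, seed = 9)
  after <- step_async(cfg, 18, p = 0.4, seed = 2)$cells
  seg <- segment_transition(cfg, after, base = 18)
  bad <- seg$segments$rule
  # flip a determined output of segment 1: the cell that observed it can no
  # longer be reproduced
  det <- seg$segments$determined[[1]]
  s_star <- which(!is.na(det))[1] - 1L
  bits <- rule_to_bits(bad[1])
  bits[s_star + 1L] <- 1L - bits[s_star + 1L]
  bad[1] <- bits_to_rule(bits)
  expect_false(verify_segmentation(seg, rules = bad))
  expect_true(verify_segmentation(seg))
})

test_that("segments partition the cells in order", {
  withr::with_seed(31, {
    for (i in 1:30) {
      n <- sample(5:60, 1)
      cfg <- random_configuration(n)
      after <- step_async(cfg, sample(0:255, 1), p = runif(1))$cells
      seg <- segment_transition(cfg, after, base = 18)
      s <- seg$segments
      expect_identical(s$start[1], 1L)
      expect_identical(s$end[seg$N1], as.integer(n))
      if (seg$N1 > 1) {
        expect_identical(s$start[-1], s$end[-seg$N1] + 1L)
      }
      expect_identical(sum(s$length), as.integer(n))
    }
  })
})
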