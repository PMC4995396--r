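test_that("initial partition spreads intermediates as evenly as integers allow", {
  expect_identical(initialPartition(6, 5), c(2L, 2L, 1L, 1L))
  expect_identical(initialPartition(0, 5), c(0L, 0L, 0L, 0L))
  expect_identical(initialPartition(8, 5), c(2L, 2L, 2L, 2L))
  expect_error(initialPartition(3, 1), "no intermediate")
  for (y0 in c(1, 7, 23, 100)) {
    for (n in c(2, 5, 9)) {
      p <- initialPartition(y0, n)
      expect_equal(sum(p), y0)
      expect_true(all(diff(p) <= 0))            # non-increasing
      expect_lte(max(p) - min(p), 1L)
    }
  }
})

test_that("closed-form total matches its boundary values and the ODE oracle", {
  ch <- chainSpec(n = 5, k = 0.3, x10 = 12, y0 = 8)
  expect_equal(analyticTotal(ch, 0), 20)
  one <- chainSpec(n = 1, k = 1, x10 = 10, y0 = 0)
  expect_equal(analyticTotal(one, log(2)), 5, tolerance = 1e-12)
  # equal-rate chain: closed form vs numerical integration on a 100-pt grid
  ch3 <- chainSpec(n = 3, k = 1, x10 = 10, y0 = 4)
  tg <- seq(0, 12, length.out = 100)
  expect_lt(max(abs(analyticTotal(ch3, tg) - odeTotals(ch3, tg)) /
                pmax(odeTotals(ch3, tg), 1e-10)), 1e-6)
  expect_equal(analyticTotal(ch3, 2), odeTotals(ch3, 2), tolerance = 1e-8)
  # strictly decreasing for a populated chain
  s <- analyticTotal(ch3, seq(0, 10, by = 0.5))
  expect_true(all(diff(s) < 0))
  # unequal rates are the ODE integrator's job
  expect_error(analyticTotal(chainSpec(2, c(1, 2), 5, 0), 1), "odeTotals")
})

test_that("ODE integration handles unequal rates and conserves mass", {
  ch <- chainSpec(n = 2, k = 1, x10 = 1, y0 = 0)
  expect_equal(odeTotals(ch, 1), 2 * exp(-1), tolerance = 1e-8)
  chU <- chainSpec(n = 4, k = c(0.5, 1, 2, 4), x10 = 30, y0 = 9)
  st <- odeTotals(chU, seq(0, 10, length.out = 40), full = TRUE)
  expect_equal(unname(rowSums(st)), rep(39, 40), tolerance = 1e-7)
  expect_true(all(diff(rowSums(st[, 1:4])) < 0))
})

test_that("chain SSA is exact: empty chain, conservation, ensemble mean, passage time", {
  empty <- ssaChain(chainSpec(3, 1, 0, 0), tEnd = 5, seed = 1)
  expect_identical(nrow(empty$events), 0L)
  expect_equal(unname(empty$finalState), c(0, 0, 0, 0))

  # every realization conserves x1+...+xn+P (recorded counts always sum to
  # the initial total)
  run <- ssaChain(chainSpec(4, 0.8, 15, 6), tEnd = 20, seed = 3,
                  recordTimes = seq(0, 20, by = 1))
  expect_equal(unname(rowSums(trajCounts(run$trajectory))), rep(21, 21))

  # ensemble mean of the total tracks the closed form (3 SE band)
  ch <- chainSpec(3, 1, 20, 0)
  grid <- seq(0.5, 8, length.out = 10)
  tr <- ensembleMean(chainSystem(ch), tEnd = 9, reps = 3000,
                     recordTimes = grid, seed = 42)
  z <- abs(trajTotal(tr) - analyticTotal(ch, grid)) / pmax(tr@totalSE, 1e-12)
  expect_true(all(z < 3))

  # single molecule through 5 steps: mean completion time = n/k
  ch1 <- chainSpec(5, 2, 1, 0)
  comp <- vapply(1:3000, function(r) {
    ev <- ssaChain(ch1, tEnd = 40, seed = r)$events
    ev$time[ev$channel == 5]
  }, numeric(1))
  se <- sd(comp) / sqrt(length(comp))
  expect_lt(abs(mean(comp) - 5 / 2), 3 * se)
})

test_that("chain SSA is reproducible under a fixed seed", {
  a <- ssaChain(chainSpec(3, 1, 10, 2), tEnd = 10, seed = 7)
  b <- ssaChain(chainSpec(3, 1, 10, 2), tEnd = 10, seed = 7)
  expect_identical(a$events, b$events)
  d <- ssaChain(chainSpec(3, 1, 10, 2), tEnd = 10, seed = 8)
  expect_false(identical(a$events, d$events))
})

test_that("chain spec validity catches inconsistent inputs", {
  expect_error(chainSpec(0, 1, 5, 0))
  expect_error(chainSpec(3, -1, 5, 0))
  expect_error(chainSpec(1, 1, 5, 3), "intermediate")
  expect_error(chainSpec(3, c(1, 2), 5, 0))   # k length 2 != 1 or n
  expect_silent(chainSpec(3, c(1, 2, 3), 5, 0))
})
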