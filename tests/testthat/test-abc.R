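makeTraj <- function(times, total, counts = NULL) {
  cnt <- if (is.null(counts)) matrix(total, ncol = 1,
                                     dimnames = list(NULL, "X"))
  else counts
  new("Trajectory", times = times, counts = cnt, se = matrix(0, 0, 0),
      total = total, totalSE = numeric(0), kind = "realization",
      reps = 1L, seed = 1L, units = "min")
}

test_that("absolute simulation error behaves like a sum of deviations", {
  tr <- makeTraj(0:10, seq(100, 0, by = -10))
  data <- data.frame(time = c(0, 5, 10), value = c(100, 50, 0))
  expect_equal(simulationError(tr, data), 0)
  off <- data.frame(time = c(1, 4, 8), value = c(90, 60, 20) + 3)
  expect_equal(simulationError(tr, off), 9)       # m * c for constant offset
  # interpolation between grid points
  half <- data.frame(time = 2.5, value = 75)
  expect_equal(simulationError(tr, half), 0)
  expect_error(simulationError(tr, data.frame(time = 12, value = 0)),
               "outside")
})

test_that("per-species scoring sums compartment errors", {
  cnt <- cbind(N = c(5, 4, 3), C = c(1, 2, 3))
  tr <- makeTraj(c(0, 1, 2), rowSums(cnt), counts = cnt)
  d <- data.frame(time = c(0, 1, 0, 1), value = c(5, 4, 0, 0),
                  species = c("N", "N", "C", "C"))
  expect_equal(simulationError(tr, d), 1 + 2)
  expect_error(simulationError(tr, data.frame(time = 0, value = 1,
                                              species = "Z")), "unknown")
})

test_that("synthetic observed tables are reproducible and decay", {
  sys <- buildRPL30(s0 = 60, y0 = 14)
  times <- c(0, 5, 10, 20, 30, 45, 60)
  a <- synthDecayData(sys, times, reps = 150, seed = 4)
  b <- synthDecayData(sys, times, reps = 150, seed = 4)
  expect_identical(a, b)
  expect_true(all(diff(attr(a, "truth")) <= 0))
  expect_equal(a$value, attr(a, "truth"))         # no noise requested
  n <- synthDecayData(sys, times, reps = 150, noiseSD = 2, seed = 4)
  expect_false(identical(n$value, a$value))
})

test_that("rejection ABC keeps the smallest errors and is deterministic", {
  sys <- buildRPL30(s0 = 40, y0 = 8)
  data <- synthDecayData(sys, c(5, 15, 30, 50), reps = 100, seed = 9)
  builder <- function(k) buildRPL30(s0 = 40, y0 = 8, k = k)
  post <- abcRejection(builder, list(k = priorUniform(0.05, 0.5)), data,
                       nDraws = 40, keep = 10, repsPerDraw = 30, seed = 21)
  expect_s4_class(post, "ABCPosterior")
  expect_identical(nrow(abcAccepted(post)), 10L)
  expect_equal(max(abcAccepted(post)$error),
               sort(post@draws$error)[10])
  expect_equal(abcBest(post)[["error"]], min(post@draws$error))
  post2 <- abcRejection(builder, list(k = priorUniform(0.05, 0.5)), data,
                        nDraws = 40, keep = 10, repsPerDraw = 30, seed = 21)
  expect_identical(abcAccepted(post), abcAccepted(post2))

  # keep = nDraws returns every draw, sorted
  all <- abcRejection(builder, list(k = priorUniform(0.05, 0.5)), data,
                      nDraws = 12, keep = 12, repsPerDraw = 10, seed = 3)
  expect_identical(nrow(abcAccepted(all)), 12L)
  expect_true(!is.unsorted(abcAccepted(all)$error))
})

test_that("builder failures score +Inf instead of aborting the run", {
  sys <- buildRPL30(s0 = 40, y0 = 8)
  data <- synthDecayData(sys, c(5, 15, 30), reps = 50, seed = 9)
  shaky <- function(k) {
    if (k > 0.2) stop("unstable parameter")
    buildRPL30(s0 = 40, y0 = 8, k = k)
  }
  post <- abcRejection(shaky, list(k = priorUniform(0.05, 0.4)), data,
                       nDraws = 20, keep = 20, repsPerDraw = 10, seed = 5)
  expect_true(any(is.infinite(post@draws$error)))
  expect_true(any(is.finite(post@draws$error)))
  expect_true(is.finite(abcBest(post)[["error"]]))
})

test_that("integer priors round their draws", {
  expect_error(priorUniform(3, 2))
  set.seed(1)
  p <- priorUniform(0, 20, integer = TRUE)
  v <- replicate(50, {
    x <- stats::runif(1, p$lower, p$upper)
    if (p$integer) round(x) else x
  })
  expect_true(all(v == round(v)))
})
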