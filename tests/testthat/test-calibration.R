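# independent evaluation of the general-branch delay for a given C2
delayGivenC2 <- function(x1, y, k, n, C2) {
  C1 <- x1 - y / (n - 1)
  logC <- log(1 + C2 * y) + lgamma(n + 1) - log(C1)
  -2 * n * pracma::lambertWp(-exp(logC / n) / (2 * n)) / k
}

test_that("optimal C2 is recovered exactly from a formula-generated delay", {
  for (C2star in c(-0.05, 0.4, 2.5)) {
    md <- delayGivenC2(20, 10, 0.126, 9, C2star)
    expect_equal(optimalC2(20, 10, 0.126, 9, md), C2star, tolerance = 1e-8)
  }
  # on the C1 = 0 locus the equation forces C2 = -1/y
  expect_equal(optimalC2(2, 16, 0.126, 9, 70), -1 / 16)
  expect_error(optimalC2(5, 1, 0.126, 9, 53, interval = c(-10, 10)),
               "no bracketing root")
})

test_that("simulation-derived optimal C2 decreases with the imaginary count", {
  reps <- 300
  k <- 0.126
  c2 <- vapply(c(5, 20, 60), function(y0) {
    recs <- measureDelaysEnsemble(chainSpec(9, k, 20, y0), reps = reps,
                                  seed = 40 + y0)
    md <- mean(recs$delay[recs$molecule_index == 1])
    optimalC2(20, y0, k, 9, md, interval = c(-50, 50))
  }, numeric(1))
  expect_true(all(diff(c2) < 0))
})

test_that("formula-vs-optimal C2 discrepancy shrinks as y grows", {
  reps <- 300
  k <- 0.126
  err <- vapply(c(2, 20, 80), function(y0) {
    recs <- measureDelaysEnsemble(chainSpec(9, k, 20, y0), reps = reps,
                                  seed = 70 + y0)
    md <- mean(recs$delay[recs$molecule_index == 1])
    abs(optimalC2(20, y0, k, 9, md, interval = c(-50, 50)) -
          coeffC2(20, y0, 9))
  }, numeric(1))
  # large error at small y, small error once the queue is populated
  expect_gt(err[1], 3 * max(err[2], err[3]))
})

test_that("alpha/beta fitting round-trips the calibrated coefficients exactly", {
  grid <- expand.grid(x1 = c(5, 10, 20, 40), y = seq(2, 60, by = 6))
  grid$C2 <- coeffC2(grid$x1, grid$y, 9)
  fit <- fitAlphaBeta(grid)
  co <- calibCoefficients(fit)
  expect_equal(unname(co), c(3.25, 7.5, 11.8, 8.2), tolerance = 1e-8)
  expect_equal(fit@perX1$alpha, alphaOf(c(5, 10, 20, 40)), tolerance = 1e-8)
  expect_equal(fit@perX1$beta, betaOf(c(5, 10, 20, 40)), tolerance = 1e-8)
})

test_that("degenerate calibration grids are rejected", {
  g1 <- data.frame(x1 = 5, y = 1:10, C2 = coeffC2(5, 1:10, 9))
  expect_error(fitAlphaBeta(g1), ">= 3 x1 levels")
  g2 <- expand.grid(x1 = c(5, 10, 20), y = c(1, 2))
  g2$C2 <- coeffC2(g2$x1, g2$y, 9)
  expect_error(fitAlphaBeta(g2), ">= 3 y levels")
})

test_that("the full measurement-to-fit pipeline runs at reduced scale", {
  cal <- calibrateC2(x1Levels = c(5, 10, 20), yFrac = c(0.5, 1, 2),
                     reps = 60, seed = 5)
  co <- calibCoefficients(cal)
  expect_true(all(is.finite(co)))
  expect_true(all(cal@perX1$beta > 0))
  # optimal C2 decreasing in y within each x1 level (soft structural check)
  for (x1v in unique(cal@grid$x1)) {
    g <- cal@grid[cal@grid$x1 == x1v, ]
    expect_true(all(diff(g$C2[order(g$y)]) < 0))
  }
})

test_that("the remainder evaluation point tau2/2 is the self-consistent optimum", {
  scan <- xiAccuracyScan(x1Levels = c(5, 20), reps = 60, seed = 3)
  expect_equal(scan$xiFrac[which.min(scan$meanRelErr)], 0.5)
})
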