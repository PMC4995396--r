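test_that("delay-equation coefficients reproduce their defining arithmetic", {
  expect_equal(coeffC1(20, 0, 9), 20)
  expect_equal(coeffC1(10, 9, 10), 9)
  expect_equal(coeffC1(2, 8, 5), 0)
  expect_equal(alphaOf(10), 4.0)
  expect_equal(alphaOf(5), 4.75)
  expect_equal(betaOf(10), 93.8)
  expect_equal(betaOf(1), 20.0)
  expect_equal(betaOf(50), 421.8)
})

test_that("C2 approximation hits the boundary identity and decreases in y", {
  # C2 = -1/y exactly where the delay equation forces 1 + C2*y = 0,
  # i.e. at the calibrated crossing y = beta(x1), for any chain length
  for (n in c(3, 5, 9)) {
    for (x1 in c(2, 8, 20)) {
      b <- betaOf(x1)
      expect_identical(coeffC2(x1, b, n), -1 / b)
    }
  }
  expect_gt(coeffC2(20, 5, 9), coeffC2(20, 30, 9))
  ys <- seq(0, 300, by = 10)
  expect_true(all(diff(coeffC2(20, ys, 9)) < 0))
  expect_equal(coeffC2(20, 0, 9), alphaOf(20) - 1 / betaOf(20))
})

test_that("closed-form delay equals bracketed bisection of the delay equation", {
  set.seed(1)
  cases <- expand.grid(x1 = c(1, 3, 10, 25, 60, 100),
                       y = c(0, 1, 5, 20, 50),
                       k = c(0.05, 0.5, 2), n = c(3, 9))
  checked <- 0
  for (i in seq_len(nrow(cases))) {
    x1 <- cases$x1[i]; y <- cases$y[i]; k <- cases$k[i]; n <- cases$n[i]
    logC <- logCOf(x1, y, n)
    if (is.na(logC)) next                       # no root on this branch
    zStar <- bisectDelayRoot(logC, n)
    if (is.na(zStar)) next                      # beyond the branch point
    tau <- tryCatch(tau2ClosedForm(x1, y, k, n), error = function(e) NA)
    if (is.na(tau)) next
    expect_equal(tau, zStar / k, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gte(checked, 100)
})

test_that("the internal Lambert W satisfies its defining identity", {
  # includes arguments within 1e-4 of the branch point -1/e, where the
  # delay states of small-copy-number systems actually land
  args <- c(-1e-8, -0.01, -0.1, -0.25, -0.33, -0.3678,
            -exp(-1) + c(1e-4, 1e-6, 1e-9))
  for (x in args) {
    w <- StateDelaySSA:::lambertW0(x)
    expect_gt(w, -1)
    expect_equal(w * exp(w), x, tolerance = 1e-10)
  }
  expect_equal(StateDelaySSA:::lambertW0(-exp(-1)), -1, tolerance = 1e-5)
})

test_that("compiled and R delay paths agree", {
  g <- expand.grid(x1 = c(1, 2, 7, 33, 90), y = c(0, 3, 17, 40),
                   k = c(0.1, 1.3), n = c(3, 6, 9))
  rVal <- tau2ClosedForm(g$x1, g$y, g$k, g$n, strict = FALSE)
  cVal <- StateDelaySSA:::.cppTau2Closed(g$x1, g$y, g$k, as.integer(g$n))
  expect_equal(rVal, as.numeric(cVal), tolerance = 1e-10)
})

test_that("delay is monotone in the state and scale-invariant in k", {
  # larger copy number -> smaller delay
  expect_gt(tau2ClosedForm(5, 0, 0.126, 9), tau2ClosedForm(40, 0, 0.126, 9))
  # more in-transit molecules -> larger delay
  expect_gt(tau2ClosedForm(20, 30, 0.126, 9), tau2ClosedForm(20, 5, 0.126, 9))
  # k and tau2 only enter via their product
  base <- tau2ClosedForm(20, 10, 1, 9)
  for (k in c(0.05, 0.1, 0.5, 1.0))
    expect_equal(tau2ClosedForm(20, 10, k, 9) * k, base, tolerance = 1e-12)
})

test_that("delay dispatch branches and error contract behave as documented", {
  # C1 = 0 branch: k*tau2 = (n-1)(1 + 1/y)
  expect_equal(tau2ClosedForm(2, 16, 0.5, 9), 8 * (1 + 1 / 16) / 0.5)
  # strict mode flags the band where no positive root exists
  expect_error(tau2ClosedForm(20, 165, 0.126, 9), "no positive root")
  expect_error(tau2ClosedForm(1, 4, 0.126, 9), "Lambert W argument")
  # relaxed mode falls back instead (engine behaviour)
  expect_gt(tau2ClosedForm(20, 165, 0.126, 9, strict = FALSE), 0)
  expect_equal(tau2ClosedForm(1, 4, 0.126, 9, strict = FALSE), 18 / 0.126)
  expect_error(tau2ClosedForm(0, 0, 1, 9), "x1")
})

test_that("the firing delay subtracts the waiting time with a positive floor", {
  t2 <- tau2ClosedForm(20, 0, 0.126, 9)
  expect_equal(stateDelay(20, 0, 0.126, 9, tau1 = 0), t2)
  expect_equal(stateDelay(20, 0, 0.126, 9, tau1 = 2), t2 - 2)
  expect_equal(stateDelay(20, 0, 0.126, 9, tau1 = t2 + 5), 1e-9)
})

test_that("harmonic-mean lumping matches direct computation", {
  expect_equal(unname(harmonicMeans(rep(3.7, 5), rep(10, 5))), c(3.7, 10))
  hm <- harmonicMeans(c(38.27, 73.44, 35.84, 9.31, 2.08),
                      c(12185600, 11852800, 9164800, 6476800, 2073600))
  expect_equal(hm[["Vbar"]], 7.623938, tolerance = 1e-6)
  expect_equal(hm[["Kbar"]], 5481279.5, tolerance = 1e-6)
  expect_error(harmonicMeans(c(1, -1), c(1, 1)))
})

test_that("effective Michaelis-Menten rate has the right limits", {
  expect_equal(mmEffectiveRate(0, 7.62, 5.48e6, 6), 7.62 / 5.48e6)
  # pseudo-first-order regime: U << Kbar changes nothing to 0.01%
  expect_equal(mmEffectiveRate(100, 7.62, 5.48e6, 6), 7.62 / 5.48e6,
               tolerance = 1e-4)
  expect_lt(mmEffectiveRate(2e6, 7.62, 5.48e6, 6),
            mmEffectiveRate(1e6, 7.62, 5.48e6, 6))
})
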