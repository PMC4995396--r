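makeBirthDeath <- function(tau = NULL) {
  sp <- c("A", "G", "P")
  if (is.null(tau)) {
    ch <- channel("decay", sp, rate = 1, type = "first", reactant = "A",
                  nu = c(A = -1))
    return(reactionSystem(sp, c(A = 1, G = 0, P = 0), list(ch),
                          totalSpecies = "A"))
  }
  ch <- channel("make", sp, rate = 2, type = "zero",
                nu = c(G = 1), u = c(G = -1, P = 1),
                delay = delayConstant(tau, imaginary = "G"))
  reactionSystem(sp, c(A = 0, G = 0, P = 0), list(ch), totalSpecies = "P")
}

test_that("propensity evaluation covers all channel kinds", {
  sys <- buildGlucosinolate(100, "full")
  a <- propensities(sys)
  expect_equal(unname(a[1]), 1.553692e-4, tolerance = 1e-6)
  expect_equal(unname(a[2:6]), rep(0, 5))     # downstream states empty
  aEmpty <- propensities(sys, state = setNames(rep(0, 7), speciesNames(sys)))
  expect_equal(as.numeric(aEmpty), rep(0, 6))
  one <- makeBirthDeath()
  expect_equal(unname(propensities(one, state = c(A = 10, G = 0, P = 0))[1]),
               10)
})

test_that("waiting-time draws are exponential with rate a0", {
  expect_identical(drawWaiting(0), Inf)
  set.seed(5)
  mu <- replicate(10000, drawWaiting(2))
  se <- sd(mu) / sqrt(length(mu))
  expect_lt(abs(mean(mu) - 0.5), 3 * se)
})

test_that("with no delayed channels the engine reduces to the plain SSA", {
  sys <- makeBirthDeath()
  times <- vapply(1:2000, function(r) {
    run <- runSDSSA(sys, tEnd = 50, seed = r, recordEvents = TRUE)
    run$events$time[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(times, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("a constant-delay channel completes exactly tau after firing", {
  sys <- makeBirthDeath(tau = 3)
  run <- runSDSSA(sys, tEnd = 10, seed = 2, recordEvents = TRUE)
  ev <- run$events
  fires <- ev$time[ev$kind == "fire"]
  comps <- ev$time[ev$kind == "complete"]
  expect_equal(comps, fires[seq_along(comps)] + 3, tolerance = 1e-12)
  # completions scheduled past tEnd stay in the queue
  expect_equal(run$queueRemaining, sum(fires > 7))
})

test_that("runs are reproducible and tEnd = 0 returns the initial state", {
  sys <- buildRPL30()
  a <- runSDSSA(sys, tEnd = 40, seed = 9, recordTimes = 0:40)
  b <- runSDSSA(sys, tEnd = 40, seed = 9, recordTimes = 0:40)
  expect_identical(trajCounts(a$trajectory), trajCounts(b$trajectory))
  z <- runSDSSA(sys, tEnd = 0, seed = 1, recordTimes = 0)
  expect_equal(unname(trajCounts(z$trajectory)[1, ]), c(77, 23, 0))
})

test_that("the reduced decay model conserves X1 + G + P in every realization", {
  sys <- buildRPL30(s0 = 60, y0 = 10)
  run <- runSDSSA(sys, tEnd = 80, seed = 4, recordTimes = seq(0, 80, by = 4))
  expect_equal(unname(rowSums(trajCounts(run$trajectory))), rep(60, 21))
})

test_that("imaginary species counts mirror the delay queue", {
  sys <- buildRPL30(s0 = 50, y0 = 0)
  run <- runSDSSA(sys, tEnd = 60, seed = 11, recordEvents = TRUE)
  ev <- run$events
  # G(t) = firings so far - completions so far, at every event time
  g <- cumsum(ifelse(ev$kind == "fire", 1, -1))
  expect_true(all(g >= 0))
  expect_equal(run$finalState[["G"]], g[length(g)])
  expect_equal(run$finalState[["G"]], run$queueRemaining)
})

test_that("ensemble summaries carry valid standard errors", {
  sys <- buildRPL30(s0 = 40, y0 = 8)
  tr <- ensembleMean(sys, tEnd = 60, reps = 200, recordTimes = c(10, 30, 50),
                     seed = 3)
  expect_s4_class(tr, "Trajectory")
  expect_identical(tr@reps, 200L)
  expect_true(all(trajSE(tr) >= 0))
  expect_gt(max(tr@totalSE), 0)   # replicate scatter shows up in the SE
})

test_that("initial imaginary molecules are pre-scheduled on [0, MT]", {
  set.seed(8)
  sched <- scheduleInitialImaginary(0, 10, "degrade")
  expect_identical(nrow(sched), 0L)
  sched <- scheduleInitialImaginary(25, 10, "degrade")
  expect_identical(nrow(sched), 25L)
  expect_true(all(sched$time >= 0 & sched$time <= 10))
  expect_false(is.unsorted(sched$time))

  # MT = delay(initial state)/D; with D = 1.7184 the scheduling window is
  # ~58% of the initial-state delay
  sys <- buildRPL30(s0 = 100, y0 = 23, k = 0.126, D = 1.7184)
  mt <- sys@initialSchedule$mt
  expect_equal(mt / tau2ClosedForm(77, 23, 0.126, 9), 1 / 1.7184,
               tolerance = 1e-12)
  expect_equal(1 / 1.7184, 0.582, tolerance = 1e-3)

  # even with nothing left to fire, queued completions are processed
  drained <- runSDSSA(buildRPL30(s0 = 5, y0 = 5), tEnd = 500, seed = 2)
  expect_equal(drained$finalState[["P"]], 5)
  expect_equal(drained$queueRemaining, 0)
})

test_that("time-varying transcription is gated by the cell-cycle profile", {
  sys <- buildSWI5(tEnd = 150)
  run <- runSDSSA(sys, tEnd = 150, seed = 6, recordEvents = TRUE)
  tx <- run$events[run$events$channel == 1 & run$events$kind == "fire", ]
  expect_gt(nrow(tx), 0)
  phase <- tx$time %% 75
  expect_true(all(phase < 49))

  silent <- buildSWI5(ndd1 = function(t) rep(0, length(t)), tEnd = 100)
  tr <- ensembleMean(silent, tEnd = 100, reps = 20,
                     recordTimes = seq(10, 100, by = 10), seed = 1)
  expect_equal(unname(trajCounts(tr)[, "mRNA_N"]), rep(0, 10))
})

test_that("stoichiometry errors are caught, not silently absorbed", {
  sp <- c("A", "B")
  bad <- channel("drain", sp, rate = 1, type = "zero", nu = c(A = -1))
  sys <- reactionSystem(sp, c(A = 1, B = 0), list(bad))
  expect_error(runSDSSA(sys, tEnd = 100, seed = 1), "negative")
})
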