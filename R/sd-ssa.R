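# The rejection delay-SSA engine (SD-SSA).  The hot loop is compiled
# (src/engine.cpp); this file holds the R surface: flattening a
# ReactionSystem for the engine, single runs, ensembles, and the small
# pure-R pieces (propensity evaluation, waiting-time draw, initial
# imaginary scheduling) that tests pin against the compiled path.

ptypeCode <- c(zero = 0L, first = 1L, mm = 2L)

# Flatten a ReactionSystem into the plain lists the C++ engine consumes.
flattenSystem <- function(system) {
  sp <- system@species
  spIdx <- function(s) match(s, sp) - 1L
  profNames <- names(system@profiles)
  chans <- lapply(system@channels, function(ch) {
    p <- ch@propensity
    d <- ch@delay
    dp <- switch(d$type,
                 none = numeric(0),
                 constant = d$tau,
                 gamma = c(d$shape, d$rate),
                 state = c(d$k, d$n, spIdx(d$x1), spIdx(d$imaginary)),
                 `state-mm` = c(d$Vbar, d$Kbar, d$n, spIdx(d$x1),
                                spIdx(d$imaginary)))
    list(ptype = ptypeCode[[p$type]],
         rate = p$rate,
         K = if (is.na(p$K)) 0 else p$K,
         pspecies = if (p$type == "zero") -1L else spIdx(p$species),
         profile = if (is.na(p$profile)) -1L
                   else match(p$profile, profNames) - 1L,
         nu = unname(ch@nu), u = unname(ch@u),
         dtype = switch(d$type, none = 0L, constant = 1L, gamma = 2L,
                        state = 3L, `state-mm` = 4L),
         dpar = dp,
         stochTau2 = isTRUE(d$stochastic),
         stochShape = 0)
  })
  sched <- system@initialSchedule
  chNames <- vapply(system@channels, function(ch) ch@name, character(1))
  list(x0 = unname(system@x0), channels = chans,
       profiles = unname(system@profiles),
       initCh = if (nrow(sched)) match(sched$channel, chNames) - 1L
                else integer(0),
       initCount = if (nrow(sched)) as.numeric(sched$count) else numeric(0),
       initMT = if (nrow(sched)) as.numeric(sched$mt) else numeric(0))
}

#' Run the state-dependent delay SSA
#'
#' One realization of the rejection delay-SSA: waiting times are drawn from
#' the total propensity; if a queued completion falls inside the drawn
#' waiting interval the completion is applied instead and the waiting time
#' discarded (propensities are recomputed); otherwise the firing channel is
#' selected categorically, its consuming stoichiometry applied, and - for
#' delayed channels - a completion is scheduled after the policy's delay
#' (state-dependent delays are computed from the state immediately before
#' the consuming update, with tau1 equal to the drawn waiting time).
#' When a queued completion coincides exactly with the drawn firing time
#' the completion wins.
#'
#' @param system a [reactionSystem()].
#' @param tEnd end time (> 0, or 0 for the initial state only).
#' @param seed integer seed; every source of randomness is derived from it.
#' @param recordTimes optional increasing grid of record times.
#' @param recordEvents if TRUE, return the per-event log.
#' @param maxEvents guard against runaway simulations.
#' @return A list with `trajectory` ([Trajectory-class] or NULL),
#'   `events` (data.frame `time`, `channel`, `kind` in fire/complete),
#'   `finalState`, `nEvents` and `queueRemaining` (completions still
#'   pending at `tEnd`).
#' @export
runSDSSA <- function(system, tEnd, seed = 1L, recordTimes = NULL,
                     recordEvents = FALSE, maxEvents = 1e8) {
  stopifnot(is(system, "ReactionSystem"), tEnd >= 0)
  validObject(system)
  flat <- flattenSystem(system)
  set.seed(seed)
  res <- .cppRunSDSSA(flat$x0, flat$channels, flat$profiles, flat$initCh,
                      flat$initCount, flat$initMT, tEnd,
                      if (is.null(recordTimes)) numeric(0) else recordTimes,
                      recordEvents, maxEvents)
  traj <- NULL
  if (!is.null(recordTimes)) {
    counts <- t(res$counts)
    colnames(counts) <- system@species
    tot <- rowSums(counts[, system@totalSpecies, drop = FALSE])
    traj <- new("Trajectory", times = as.numeric(recordTimes),
                counts = counts, se = matrix(0, 0, 0), total = tot,
                totalSE = numeric(0), kind = "realization", reps = 1L,
                seed = as.integer(seed), units = system@units)
  }
  events <- data.frame(time = res$eventTime, channel = res$eventChannel,
                       kind = c("fire", "complete")[res$eventKind + 1L])
  fs <- stats::setNames(res$finalState, system@species)
  list(trajectory = traj, events = events, finalState = fs,
       nEvents = res$nEvents, queueRemaining = res$queueRemaining)
}

#' Ensemble mean of SD-SSA realizations
#'
#' Runs `reps` independent realizations and returns the per-species mean
#' and standard error on the record grid, plus the mean and SE of the
#' system's total copy number.
#'
#' @inheritParams runSDSSA
#' @param reps number of replicates (>= 1).
#' @param recordTimes increasing record grid (required).
#' @return A [Trajectory-class] with `kind = "mean"`.
#' @export
ensembleMean <- function(system, tEnd, reps, recordTimes, seed = 1L,
                         maxEvents = 1e8) {
  stopifnot(is(system, "ReactionSystem"), reps >= 1, length(recordTimes) >= 1)
  validObject(system)
  flat <- flattenSystem(system)
  totIdx <- match(system@totalSpecies, system@species) - 1L
  set.seed(seed)
  res <- .cppRunEnsemble(flat$x0, flat$channels, flat$profiles, flat$initCh,
                         flat$initCount, flat$initMT, tEnd,
                         as.numeric(recordTimes), as.integer(reps),
                         as.integer(totIdx), maxEvents)
  counts <- t(res$mean)
  colnames(counts) <- system@species
  se <- t(res$se)
  colnames(se) <- system@species
  new("Trajectory", times = as.numeric(recordTimes), counts = counts,
      se = se, total = as.numeric(res$totalMean),
      totalSE = as.numeric(res$totalSE), kind = "mean",
      reps = as.integer(reps), seed = as.integer(seed),
      units = system@units)
}

#' Propensity functions of a system state
#'
#' Evaluates every channel's propensity at the given state and time:
#' mass action `k*x` (first order), constant rate (zero order),
#' Michaelis-Menten `V*x/(K + x)`, each multiplied by its time-varying
#' profile factor if one is attached.
#'
#' @param system a [reactionSystem()].
#' @param state named counts (defaults to the initial state).
#' @param t time at which time-varying factors are evaluated.
#' @return Named numeric of propensities with attribute `a0` (their sum).
#' @export
propensities <- function(system, state = initialState(system), t = 0) {
  stopifnot(all(state >= 0))
  profVal <- vapply(system@profiles, function(pr) {
    i <- findInterval(t, pr$times)
    pr$values[max(i, 1L)]
  }, numeric(1))
  a <- vapply(system@channels, function(ch) {
    p <- ch@propensity
    v <- switch(p$type,
                zero = p$rate,
                first = p$rate * state[[p$species]],
                mm = p$rate * state[[p$species]] / (p$K + state[[p$species]]))
    if (!is.na(p$profile)) v <- v * profVal[[p$profile]]
    v
  }, numeric(1))
  names(a) <- vapply(system@channels, function(ch) ch@name, character(1))
  attr(a, "a0") <- sum(a)
  a
}

#' Waiting time of the next reaction
#'
#' Draws mu = -log(r1)/a0 with r1 ~ U(0,1); returns `Inf` when the total
#' propensity is zero (the engine then jumps to the next queued
#' completion).
#'
#' @param a0 total propensity (>= 0).
#' @return The exponential waiting time.
#' @export
drawWaiting <- function(a0) {
  stopifnot(a0 >= 0)
  if (a0 == 0) return(Inf)
  -log(stats::runif(1)) / a0
}

#' Pre-schedule completions for initially present imaginary molecules
#'
#' Molecules already in transit at t = 0 (the initial imaginary species
#' count y0) have covered part of the lumped chain, so their completions
#' are scheduled i.i.d. uniformly on `[0, MT]` with
#' `MT = delay(x10, y0, k, n) / D`: the initial-state delay shortened by a
#' factor `D > 1`.
#'
#' @param y0 number of initial imaginary molecules (>= 0).
#' @param MT upper end of the scheduling interval (> 0 when `y0 > 0`).
#' @param channelName the delayed channel whose completions these are.
#' @return data.frame (`channel`, `time`) of scheduled completions, sorted
#'   by time; zero rows when `y0 = 0`.
#' @export
scheduleInitialImaginary <- function(y0, MT, channelName) {
  stopifnot(y0 >= 0, y0 == 0 || MT > 0)
  if (y0 == 0)
    return(data.frame(channel = character(), time = numeric()))
  times <- sort(stats::runif(y0, 0, MT))
  data.frame(channel = channelName, time = times)
}
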