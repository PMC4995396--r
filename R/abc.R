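# ABC rejection inference for delay models, plus the synthetic-data
# generator that stands in for experimental decay/expression curves.

#' Absolute simulation error against observed data
#'
#' Sum over the observation times of |simulated mean total - observed
#' value|.  Observation times that are not on the simulation grid are
#' linearly interpolated.
#'
#' @param traj a [Trajectory-class] (typically an ensemble mean).
#' @param data data.frame with columns `time` and `value`; an optional
#'   `species` column scores each observation against that species' mean
#'   (so nucleus and cytosol series are summed into one criterion) instead
#'   of the total.
#' @return The absolute error (a single number).
#' @export
simulationError <- function(traj, data) {
  stopifnot(is(traj, "Trajectory"), all(c("time", "value") %in% names(data)))
  if (min(data$time) < min(traj@times) - 1e-9 ||
      max(data$time) > max(traj@times) + 1e-9)
    stop("observed times outside the simulated grid")
  if ("species" %in% names(data)) {
    bad <- setdiff(unique(data$species), colnames(traj@counts))
    if (length(bad)) stop("unknown species in data: ",
                          paste(bad, collapse = ", "))
    sim <- mapply(function(tt, sp)
      stats::approx(traj@times, traj@counts[, sp], xout = tt)$y,
      data$time, data$species)
  } else {
    sim <- stats::approx(traj@times, traj@total, xout = data$time)$y
  }
  sum(abs(sim - data$value))
}

#' Synthetic observed decay/expression data
#'
#' Generates an observed table from a known ground-truth model: the
#' ensemble-mean total at the requested times, plus optional additive
#' Gaussian noise.  This emulates population-average decay measurements
#' (a large pool of cells sampled at a handful of time points) and is the
#' stand-in for experimental curves that exist only as published figures.
#'
#' @param system a [reactionSystem()] (the ground truth).
#' @param times observation times (increasing).
#' @param reps replicates behind the ensemble mean.
#' @param noiseSD standard deviation of the additive noise (0 = none).
#' @param seed integer seed.
#' @return data.frame with `time`, `value` and attribute `truth` (the
#'   noiseless means).
#' @export
synthDecayData <- function(system, times, reps = 1000L, noiseSD = 0,
                           seed = 1L) {
  stopifnot(!is.unsorted(times), noiseSD >= 0)
  tEnd <- max(times) * 1.001 + 1e-9
  traj <- ensembleMean(system, tEnd = tEnd, reps = reps,
                       recordTimes = times, seed = seed)
  truth <- traj@total
  value <- truth
  if (noiseSD > 0) value <- value + stats::rnorm(length(value), 0, noiseSD)
  out <- data.frame(time = times, value = value)
  attr(out, "truth") <- truth
  out
}

#' Uniform prior specification
#'
#' @param lower,upper bounds (lower < upper).
#' @param integer round draws to integers (for counts).
#' @return A prior description for [abcRejection()].
#' @export
priorUniform <- function(lower, upper, integer = FALSE) {
  stopifnot(lower < upper)
  list(dist = "uniform", lower = lower, upper = upper, integer = integer)
}

#' ABC rejection sampling
#'
#' Plain rejection ABC: draw parameter vectors from the priors, simulate
#' the built model as an ensemble mean over `repsPerDraw` replicates,
#' score each draw by [simulationError()], retain the `keep` smallest
#' errors, and report the minimal-error vector as the point estimate.
#'
#' @param builder function taking the named parameters and returning a
#'   [reactionSystem()]; a draw whose builder fails is scored `+Inf` and
#'   recorded.
#' @param priors named list of [priorUniform()] specifications.
#' @param data observed table (`time`, `value`).
#' @param nDraws number of prior draws (>= `keep`).
#' @param keep accepted-set size (default 150).
#' @param repsPerDraw ensemble size per draw (default 200).
#' @param seed integer seed; draws and simulations are reproducible.
#' @return An [ABCPosterior-class].
#' @export
abcRejection <- function(builder, priors, data, nDraws, keep = 150L,
                         repsPerDraw = 200L, seed = 1L) {
  stopifnot(nDraws >= keep, keep >= 1L, repsPerDraw >= 1L)
  set.seed(seed)
  drawOne <- function() {
    vapply(priors, function(p) {
      v <- stats::runif(1, p$lower, p$upper)
      if (isTRUE(p$integer)) v <- round(v)
      v
    }, numeric(1))
  }
  draws <- vapply(seq_len(nDraws), function(i) drawOne(),
                  numeric(length(priors)))
  params <- if (is.matrix(draws)) t(draws) else matrix(draws, ncol = 1L)
  colnames(params) <- names(priors)
  times <- data$time
  tEnd <- max(times) * 1.001 + 1e-9
  simSeeds <- sample.int(2^31 - 2, nDraws)
  errors <- vapply(seq_len(nDraws), function(i) {
    sys <- tryCatch(do.call(builder, as.list(params[i, ])),
                    error = function(e) NULL)
    if (is.null(sys)) return(Inf)
    traj <- tryCatch(
      ensembleMean(sys, tEnd = tEnd, reps = repsPerDraw,
                   recordTimes = times, seed = simSeeds[i]),
      error = function(e) NULL)
    if (is.null(traj)) return(Inf)
    simulationError(traj, data)
  }, numeric(1))
  draws <- data.frame(params, error = errors, check.names = FALSE)
  ord <- order(draws$error)
  accepted <- draws[ord[seq_len(min(keep, nDraws))], , drop = FALSE]
  rownames(accepted) <- NULL
  bestRow <- accepted[1L, , drop = FALSE]
  best <- stats::setNames(as.numeric(bestRow), names(bestRow))
  new("ABCPosterior", draws = draws, accepted = accepted, best = best,
      keep = as.integer(keep), seed = as.integer(seed))
}
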