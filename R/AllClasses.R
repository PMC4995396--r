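#' @import methods
NULL

# ---------------------------------------------------------------------------
#' ChainSpec: an n-step sequential reaction chain
#'
#' Describes the multistep chain X1 -> X2 -> ... -> Xn -> P with per-step
#' rate constants, an initial count in the first state and a total initial
#' count spread over the intermediate states X2..Xn.
#'
#' @slot n integer, number of sequential steps (>= 1).
#' @slot k numeric, per-step rate constants (length 1, recycled, or length n).
#' @slot x10 integer, initial copy number in state X1.
#' @slot y0 integer, total initial copy number in the intermediate states;
#'   must be 0 when `n = 1` (no intermediates exist).
#' @exportClass ChainSpec
setClass("ChainSpec",
         representation(n = "integer", k = "numeric",
                        x10 = "integer", y0 = "integer"))

setValidity("ChainSpec", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "n must be a single integer >= 1")
  if (!length(object@k) %in% c(1L, object@n))
    msg <- c(msg, "k must have length 1 or n")
  if (any(!is.finite(object@k)) || any(object@k <= 0))
    msg <- c(msg, "all rate constants must be finite and > 0")
  if (length(object@x10) != 1L || is.na(object@x10) || object@x10 < 0L)
    msg <- c(msg, "x10 must be a single non-negative integer")
  if (length(object@y0) != 1L || is.na(object@y0) || object@y0 < 0L)
    msg <- c(msg, "y0 must be a single non-negative integer")
  if (length(object@n) == 1L && !is.na(object@n) &&
      object@n == 1L && length(object@y0) == 1L &&
      !is.na(object@y0) && object@y0 > 0L)
    msg <- c(msg, "y0 must be 0 when n = 1: a one-step chain has no intermediate states")
  if (length(msg)) msg else TRUE
})

#' Construct a ChainSpec
#'
#' @param n number of sequential steps (integer >= 1).
#' @param k per-step rate constant (1/time); a scalar (equal rates) or a
#'   vector of length `n`.
#' @param x10 initial copy number in state X1.
#' @param y0 total initial copy number in the intermediates X2..Xn, spread
#'   by [initialPartition()].
#' @return A [ChainSpec-class] object.
#' @examples
#' chainSpec(n = 9, k = 0.126, x10 = 77, y0 = 23)
#' @export
chainSpec <- function(n, k, x10 = 0, y0 = 0) {
  new("ChainSpec", n = as.integer(n), k = as.numeric(k),
      x10 = as.integer(x10), y0 = as.integer(y0))
}

#' @describeIn chainSpec number of steps
#' @param chain a `ChainSpec`
#' @export
nSteps <- function(chain) chain@n

#' @describeIn chainSpec per-step rate constants, recycled to length `n`
#' @export
rateConstants <- function(chain) rep_len(chain@k, chain@n)

#' @describeIn chainSpec TRUE if every step has the same rate constant
#' @export
hasEqualRates <- function(chain) length(unique(rateConstants(chain))) == 1L

#' @describeIn chainSpec initial counts (x10, then the intermediate partition)
#' @export
initialCounts <- function(chain) {
  inter <- if (chain@n >= 2L) initialPartition(chain@y0, chain@n) else integer(0)
  stats::setNames(c(chain@x10, inter),
                  paste0("X", seq_len(chain@n)))
}

setMethod("show", "ChainSpec", function(object) {
  k <- rateConstants(object)
  cat("ChainSpec: ", object@n, "-step chain\n", sep = "")
  cat("  rates:", if (hasEqualRates(object)) paste0("k = ", k[1L], " (equal)")
      else paste(signif(k, 4), collapse = ", "), "\n")
  cat("  initial counts: x10 =", object@x10, ", y0 =", object@y0, "\n")
})

# ---------------------------------------------------------------------------
#' Channel: one reaction channel of a delayed-SSA system
#'
#' A channel has a propensity specification, a consuming stoichiometry `nu`
#' applied when it fires, and - for delayed channels - a manifesting
#' stoichiometry `u` applied when the scheduled completion is reached,
#' together with a delay policy (`none`, `constant`, `distributed` or
#' `state-dependent`).
#'
#' @slot name character, channel label.
#' @slot propensity list with fields `type` ("zero", "first", "mm"),
#'   `rate`, `K` (MM only), `species` (reactant name) and `profile`
#'   (name of a time-varying rate factor or NA).
#' @slot nu numeric, consuming stoichiometry (named by species).
#' @slot u numeric, manifesting stoichiometry.
#' @slot delay list with fields `type` ("none", "constant", "gamma",
#'   "state" or "state-mm") plus the policy parameters.
#' @exportClass Channel
setClass("Channel",
         representation(name = "character", propensity = "list",
                        nu = "numeric", u = "numeric", delay = "list"))

setValidity("Channel", function(object) {
  msg <- character()
  p <- object@propensity
  if (!p$type %in% c("zero", "first", "mm"))
    msg <- c(msg, "propensity type must be 'zero', 'first' or 'mm'")
  if (!is.finite(p$rate) || p$rate < 0)
    msg <- c(msg, "propensity rate must be finite and >= 0")
  if (p$type == "mm" && (!is.finite(p$K) || p$K <= 0))
    msg <- c(msg, "Michaelis-Menten K must be finite and > 0")
  d <- object@delay
  if (!d$type %in% c("none", "constant", "gamma", "state", "state-mm"))
    msg <- c(msg, "unknown delay type")
  if (d$type == "none" && any(object@u != 0))
    msg <- c(msg, "non-delayed channels must have an empty manifesting stoichiometry")
  if (d$type != "none") {
    g <- d$imaginary
    if (is.null(g) || !g %in% names(object@nu))
      msg <- c(msg, "a delayed channel must name its imaginary species")
    else if (!(object@nu[g] > 0 && object@u[g] < 0))
      msg <- c(msg, "the imaginary species must be incremented by nu and decremented by u")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a reaction channel
#'
#' @param name channel label.
#' @param species character vector of all species names in the system (the
#'   stoichiometries are expanded to this set).
#' @param rate rate constant (zero/first order) or maximal rate V (MM).
#' @param type propensity type: `"zero"` (constant rate), `"first"`
#'   (mass action, `rate * x`), or `"mm"` (`rate * x / (K + x)`).
#' @param reactant reactant species name (ignored for `type = "zero"`).
#' @param K Michaelis-Menten constant (molecules), for `type = "mm"`.
#' @param profile name of a time-varying rate factor, or `NA`.
#' @param nu named numeric, consuming stoichiometry (state change at firing).
#' @param u named numeric, manifesting stoichiometry (state change at
#'   completion); empty for non-delayed channels.
#' @param delay delay policy, one of `delayNone()`, `delayConstant()`,
#'   `delayGamma()`, `delayState()`, `delayStateMM()`.
#' @return A [Channel-class] object.
#' @export
channel <- function(name, species, rate, type = c("first", "zero", "mm"),
                    reactant = NA_character_, K = NA_real_,
                    profile = NA_character_, nu = numeric(),
                    u = numeric(), delay = delayNone()) {
  type <- match.arg(type)
  full <- function(v) {
    out <- stats::setNames(numeric(length(species)), species)
    if (length(v)) {
      bad <- setdiff(names(v), species)
    if (length(bad)) stop("unknown species in stoichiometry: ",
                          paste(bad, collapse = ", "))
      out[names(v)] <- v
    }
    out
  }
  new("Channel", name = name,
      propensity = list(type = type, rate = rate, K = K,
                        species = reactant, profile = profile),
      nu = full(nu), u = full(u), delay = delay)
}

#' Delay policies for reaction channels
#'
#' `delayNone()` marks an elementary channel; `delayConstant()` schedules
#' completions a fixed time after firing; `delayGamma()` draws the delay
#' from a gamma distribution; `delayState()` computes the delay from the
#' current state via the Lambert-W closed form ([tau2ClosedForm()]) for a
#' lumped `n`-step chain with per-step rate `k`; `delayStateMM()` does the
#' same with an effective per-step rate derived from lumped
#' Michaelis-Menten parameters ([mmEffectiveRate()]).
#'
#' @param tau constant delay (time units).
#' @param shape,rate gamma distribution parameters.
#' @param k per-step rate constant of the lumped chain.
#' @param n step count of the lumped chain (>= 2).
#' @param x1 species whose count enters the delay formula as x1 (evaluated
#'   before the consuming update, so it still counts the firing molecule).
#' @param imaginary name of the imaginary (in-transit) species G.
#' @param Vbar,Kbar harmonic-mean Michaelis-Menten parameters over the
#'   lumped steps (see [harmonicMeans()]).
#' @param stochastic if TRUE, sample tau2 from an Erlang distribution whose
#'   mean is the deterministic closed-form value (shape `n - 1`).
#' @return A list describing the delay policy.
#' @name delayPolicies
NULL

#' @rdname delayPolicies
#' @export
delayNone <- function() list(type = "none", imaginary = NULL)

#' @rdname delayPolicies
#' @export
delayConstant <- function(tau, imaginary) {
  stopifnot(is.finite(tau), tau >= 0)
  list(type = "constant", tau = tau, imaginary = imaginary)
}

#' @rdname delayPolicies
#' @export
delayGamma <- function(shape, rate, imaginary) {
  stopifnot(shape > 0, rate > 0)
  list(type = "gamma", shape = shape, rate = rate, imaginary = imaginary)
}

#' @rdname delayPolicies
#' @export
delayState <- function(k, n, x1, imaginary, stochastic = FALSE) {
  stopifnot(k > 0, n >= 2)
  list(type = "state", k = k, n = as.integer(n), x1 = x1,
       imaginary = imaginary, stochastic = stochastic)
}

#' @rdname delayPolicies
#' @export
delayStateMM <- function(Vbar, Kbar, n, x1, imaginary, stochastic = FALSE) {
  stopifnot(Vbar > 0, Kbar > 0, n >= 2)
  list(type = "state-mm", Vbar = Vbar, Kbar = Kbar, n = as.integer(n),
       x1 = x1, imaginary = imaginary, stochastic = stochastic)
}

# ---------------------------------------------------------------------------
#' ReactionSystem: a ready-to-simulate delayed-SSA system
#'
#' @slot species character, species names (real and imaginary).
#' @slot x0 numeric, named initial copy numbers.
#' @slot channels list of [Channel-class] objects.
#' @slot profiles named list of time-varying rate factors, each a list with
#'   `times` (breakpoints) and `values` (the factor held from each
#'   breakpoint to the next).
#' @slot initialSchedule data.frame with columns `channel`, `count`, `mt`:
#'   for each entry, `count` completions of the named delayed channel are
#'   pre-scheduled uniformly on `[0, mt]` at the start of every realization.
#' @slot totalSpecies character, the species whose sum is reported as the
#'   "total molecule number" of the system.
#' @slot units character, time unit label carried into outputs.
#' @exportClass ReactionSystem
setClass("ReactionSystem",
         representation(species = "character", x0 = "numeric",
                        channels = "list", profiles = "list",
                        initialSchedule = "data.frame",
                        totalSpecies = "character", units = "character"))

setValidity("ReactionSystem", function(object) {
  msg <- character()
  if (anyDuplicated(object@species))
    msg <- c(msg, "duplicated species names")
  if (!identical(names(object@x0), object@species))
    msg <- c(msg, "x0 must be named exactly by species")
  if (any(object@x0 < 0)) msg <- c(msg, "initial counts must be >= 0")
  for (ch in object@channels) {
    if (!is(ch, "Channel")) { msg <- c(msg, "channels must be Channel objects"); break }
    if (!identical(names(ch@nu), object@species))
      msg <- c(msg, paste0("channel '", ch@name, "' stoichiometry does not match species"))
    p <- ch@propensity
    if (p$type != "zero" && !p$species %in% object@species)
      msg <- c(msg, paste0("channel '", ch@name, "' reactant not a species"))
    if (!is.na(p$profile) && !p$profile %in% names(object@profiles))
      msg <- c(msg, paste0("channel '", ch@name, "' references unknown profile"))
  }
  if (nrow(object@initialSchedule)) {
    if (!all(c("channel", "count", "mt") %in% names(object@initialSchedule)))
      msg <- c(msg, "initialSchedule needs columns channel, count, mt")
    else if (any(object@initialSchedule$mt <= 0 & object@initialSchedule$count > 0))
      msg <- c(msg, "initialSchedule mt must be > 0")
  }
  if (!all(object@totalSpecies %in% object@species))
    msg <- c(msg, "totalSpecies must be a subset of species")
  if (length(msg)) msg else TRUE
})

#' Construct a ReactionSystem
#'
#' @param species character vector of species names.
#' @param x0 named initial copy numbers (missing species default to 0).
#' @param channels list of [channel()] objects.
#' @param profiles named list of time-varying rate factors (`times`,
#'   `values` step tables).
#' @param initialSchedule data.frame (`channel`, `count`, `mt`) of
#'   pre-scheduled completions, see [scheduleInitialImaginary()].
#' @param totalSpecies species whose sum is the reported total count
#'   (defaults to all non-product species, i.e. all species).
#' @param units time unit label.
#' @return A [ReactionSystem-class] object.
#' @export
reactionSystem <- function(species, x0, channels, profiles = list(),
                           initialSchedule = NULL, totalSpecies = species,
                           units = "time") {
  full <- stats::setNames(numeric(length(species)), species)
  full[names(x0)] <- x0
  if (is.null(initialSchedule))
    initialSchedule <- data.frame(channel = character(), count = numeric(),
                                  mt = numeric())
  new("ReactionSystem", species = species, x0 = full, channels = channels,
      profiles = profiles, initialSchedule = initialSchedule,
      totalSpecies = totalSpecies, units = units)
}

setMethod("show", "ReactionSystem", function(object) {
  cat("ReactionSystem with", length(object@species), "species and",
      length(object@channels), "channels\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  for (ch in object@channels)
    cat("  -", ch@name, paste0("[", ch@propensity$type, ", delay: ",
                               ch@delay$type, "]"), "\n")
  if (nrow(object@initialSchedule))
    cat("  pre-scheduled completions:",
        sum(object@initialSchedule$count), "\n")
})

#' @describeIn reactionSystem species accessor
#' @param system a `ReactionSystem`
#' @export
speciesNames <- function(system) system@species

#' @describeIn reactionSystem initial state accessor
#' @export
initialState <- function(system) system@x0

# ---------------------------------------------------------------------------
#' Trajectory: recorded counts of one realization or an ensemble mean
#'
#' @slot times numeric, strictly increasing record times.
#' @slot counts matrix (time x species) of copy numbers; for an ensemble,
#'   the per-species means.
#' @slot se matrix of standard errors (ensembles) or a 0-row matrix.
#' @slot total numeric, total copy number over the system's `totalSpecies`.
#' @slot totalSE numeric, its standard error (ensembles).
#' @slot kind character, "realization" or "mean".
#' @slot reps integer, number of replicates behind an ensemble mean.
#' @slot seed integer, the seed the run was started from.
#' @slot units character, time unit label.
#' @exportClass Trajectory
setClass("Trajectory",
         representation(times = "numeric", counts = "matrix", se = "matrix",
                        total = "numeric", totalSE = "numeric",
                        kind = "character", reps = "integer",
                        seed = "integer", units = "character"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@counts))
    msg <- c(msg, "times and counts rows differ")
  if (is.unsorted(object@times, strictly = FALSE))
    msg <- c(msg, "times must be non-decreasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!object@kind %in% c("realization", "mean"))
    msg <- c(msg, "kind must be 'realization' or 'mean'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory (", object@kind,
      if (object@kind == "mean") paste0(" of ", object@reps, " replicates"),
      "): ", length(object@times), " time points, ",
      ncol(object@counts), " species [seed ", object@seed, "]\n", sep = "")
})

#' Accessors for Trajectory objects
#'
#' @param x a [Trajectory-class]
#' @return `trajTimes`: record times; `trajCounts`: time-by-species count
#'   matrix; `trajTotal`: total copy number over the system's total-species
#'   set; `trajSE`: standard errors (ensembles).
#' @name trajectory-accessors
NULL

#' @rdname trajectory-accessors
#' @export
trajTimes <- function(x) x@times

#' @rdname trajectory-accessors
#' @export
trajCounts <- function(x) x@counts

#' @rdname trajectory-accessors
#' @export
trajTotal <- function(x) x@total

#' @rdname trajectory-accessors
#' @export
trajSE <- function(x) x@se

#' Tidy view of a trajectory
#'
#' @param x a [Trajectory-class]
#' @return A data.frame with columns `time`, `species`, `count`,
#'   `replicate`, `seed` (ensembles add `se`).
#' @export
asTidyFrame <- function(x) {
  sp <- colnames(x@counts)
  out <- data.frame(
    time = rep(x@times, times = length(sp)),
    species = rep(sp, each = length(x@times)),
    count = as.vector(x@counts),
    replicate = if (x@kind == "mean") "mean" else "1",
    seed = x@seed, stringsAsFactors = FALSE)
  if (x@kind == "mean" && nrow(x@se)) out$se <- as.vector(x@se)
  out
}

# ---------------------------------------------------------------------------
#' CalibrationResult: re-derived delay-coefficient approximation
#'
#' @slot grid data.frame of per-state optimal C2 values (`x1`, `y`,
#'   `delay`, `C2opt`, `C2formula`).
#' @slot perX1 data.frame of per-x1 fitted alpha/beta.
#' @slot coefficients named numeric (a0, a1, b0, b1) of the fits
#'   alpha(x1) = a0 + a1/x1 and beta(x1) = b0 + b1*x1.
#' @slot residuals list with the per-stage residuals.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
         representation(grid = "data.frame", perX1 = "data.frame",
                        coefficients = "numeric", residuals = "list"))

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult over", nrow(object@grid), "states,",
      nrow(object@perX1), "x1 levels\n")
  co <- object@coefficients
  cat(sprintf("  alpha(x1) = %.4g + %.4g/x1\n", co["a0"], co["a1"]))
  cat(sprintf("  beta(x1)  = %.4g + %.4g*x1\n", co["b0"], co["b1"]))
})

#' @describeIn fitAlphaBeta extract the fitted (a0, a1, b0, b1)
#' @param object a `CalibrationResult`
#' @export
calibCoefficients <- function(object) object@coefficients

# ---------------------------------------------------------------------------
#' ABCPosterior: accepted draws of a rejection-ABC fit
#'
#' @slot draws data.frame of all sampled parameter vectors and their
#'   simulation errors.
#' @slot accepted data.frame of the retained (smallest-error) draws.
#' @slot best named numeric, the minimal-error parameter vector.
#' @slot keep integer, configured acceptance count.
#' @slot seed integer.
#' @exportClass ABCPosterior
setClass("ABCPosterior",
         representation(draws = "data.frame", accepted = "data.frame",
                        best = "numeric", keep = "integer", seed = "integer"))

setValidity("ABCPosterior", function(object) {
  msg <- character()
  if (nrow(object@accepted) != min(object@keep, nrow(object@draws)))
    msg <- c(msg, "accepted set size must equal the keep count")
  if (nrow(object@accepted) &&
      abs(min(object@accepted$error) - object@best["error"]) > 1e-12)
    msg <- c(msg, "best error must be the minimum over the accepted set")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ABCPosterior", function(object) {
  cat("ABCPosterior:", nrow(object@draws), "draws,",
      nrow(object@accepted), "accepted [seed", object@seed, "]\n")
  b <- object@best
  cat("  best:", paste(sprintf("%s = %.4g", names(b), b), collapse = ", "), "\n")
})

#' Accessors for ABCPosterior objects
#'
#' @param x an [ABCPosterior-class]
#' @return `abcBest`: the minimal-error parameter vector; `abcAccepted`:
#'   the accepted draws with their errors.
#' @name abc-accessors
NULL

#' @rdname abc-accessors
#' @export
abcBest <- function(x) x@best

#' @rdname abc-accessors
#' @export
abcAccepted <- function(x) x@accepted
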