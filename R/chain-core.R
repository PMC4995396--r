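# Exact representations of the multistep chain: closed-form total count,
# ODE integration, and Gillespie simulation.  These are the ground truth
# against which every delayed reduction is judged.

#' Partition an intermediate total over the chain states
#'
#' Spreads `y0` molecules over the `n - 1` intermediate states X2..Xn as
#' evenly as integers allow: the counts are non-increasing and differ by at
#' most 1 (e.g. `y0 = 6`, `n = 5` gives `2, 2, 1, 1`), mirroring the
#' deterministic assumption of equal occupancy.
#'
#' @param y0 non-negative integer total over the intermediates.
#' @param n chain length (>= 2 whenever `y0 > 0`).
#' @return Integer vector of length `n - 1` with the counts of X2..Xn.
#' @examples
#' initialPartition(6, 5)   # 2 2 1 1
#' @export
initialPartition <- function(y0, n) {
  y0 <- as.integer(y0); n <- as.integer(n)
  stopifnot(y0 >= 0L)
  if (n < 2L) {
    if (y0 > 0L) stop("n < 2: there are no intermediate states to hold y0 > 0")
    return(integer(0))
  }
  m <- n - 1L
  base <- y0 %/% m
  extra <- y0 %% m
  as.integer(base + (seq_len(m) <= extra))
}

#' Closed-form expected total copy number of an equal-rate chain
#'
#' For the chain X1 -> ... -> Xn -> P with equal per-step rate k, the
#' expected total count of molecules still in the chain at time t is
#' \deqn{s(t) = e^{-kt}\Big[x_{10}\sum_{i=0}^{n-1}\frac{(kt)^i}{i!}
#'   + \frac{y_0}{n-1}\sum_{i=0}^{n-2}(n-1-i)\frac{(kt)^i}{i!}\Big],}
#' the X1-seeded Erlang survival series plus the contribution of the
#' uniformly partitioned intermediates.  Evaluated through regularized
#' Poisson tails (`ppois`) for numerical stability.
#'
#' @param chain a [chainSpec()] with equal rates.
#' @param t vector of times (>= 0).
#' @return Numeric vector of expected totals, `s(0) = x10 + y0`.
#' @examples
#' ch <- chainSpec(n = 3, k = 1, x10 = 10, y0 = 4)
#' analyticTotal(ch, c(0, 1, 2))
#' @export
analyticTotal <- function(chain, t) {
  stopifnot(is(chain, "ChainSpec"), all(t >= 0))
  if (!hasEqualRates(chain))
    stop("analyticTotal requires equal per-step rates; use odeTotals for unequal rates")
  n <- chain@n
  k <- rateConstants(chain)[1L]
  z <- k * t
  tail1 <- stats::ppois(n - 1L, z)
  s <- chain@x10 * tail1
  if (n >= 2L && chain@y0 > 0L) {
    s2 <- (n - 1L) * stats::ppois(n - 2L, z) -
      z * (if (n >= 3L) stats::ppois(n - 3L, z) else 0)
    s <- s + chain@y0 / (n - 1L) * s2
  }
  s
}

#' ODE integration of the chain
#'
#' Integrates dx1/dt = -k1 x1, dxi/dt = k_{i-1} x_{i-1} - k_i x_i,
#' dP/dt = k_n x_n with `deSolve::lsoda`.  Supports unequal rates; the
#' intermediates start from `y0 / (n - 1)` each (the deterministic
#' counterpart of [initialPartition()]).
#'
#' @param chain a [chainSpec()].
#' @param tGrid increasing time grid starting at >= 0.
#' @param full if TRUE return the full state matrix (x1..xn, P) instead of
#'   the totals.
#' @return Numeric vector of totals on the grid (or a matrix if `full`).
#' @export
odeTotals <- function(chain, tGrid, full = FALSE) {
  stopifnot(is(chain, "ChainSpec"), !is.unsorted(tGrid), all(tGrid >= 0))
  n <- chain@n
  k <- rateConstants(chain)
  if (any(!is.finite(k))) stop("non-finite rate constants")
  y0 <- c(chain@x10,
          if (n >= 2L) rep(chain@y0 / (n - 1), n - 1L) else numeric(0), 0)
  deriv <- function(t, x, p) {
    flux <- k * x[seq_len(n)]
    dx <- c(-flux[1L],
            if (n >= 2L) flux[seq_len(n - 1L)] - flux[-1L] else numeric(0),
            flux[n])
    list(dx)
  }
  grid <- tGrid
  prepend <- grid[1L] > 0
  if (prepend) grid <- c(0, grid)
  sol <- deSolve::lsoda(y0, grid, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  state <- sol[, -1L, drop = FALSE]
  if (prepend) state <- state[-1L, , drop = FALSE]
  colnames(state) <- c(paste0("X", seq_len(n)), "P")
  if (full) return(state)
  rowSums(state[, seq_len(n), drop = FALSE])
}

# Translate a ChainSpec into its ReactionSystem twin: n first-order
# channels X_i -> X_{i+1} (the last produces P), no delays.
#' @describeIn ssaChain the chain as a plain-SSA [reactionSystem()]
#' @export
chainSystem <- function(chain) {
  stopifnot(is(chain, "ChainSpec"))
  n <- chain@n
  k <- rateConstants(chain)
  sp <- c(paste0("X", seq_len(n)), "P")
  chans <- lapply(seq_len(n), function(i) {
    nu <- stats::setNames(c(-1, 1), c(sp[i], sp[i + 1L]))
    channel(name = paste0("step", i), species = sp, rate = k[i],
            type = "first", reactant = sp[i], nu = nu)
  })
  reactionSystem(species = sp, x0 = c(initialCounts(chain), P = 0),
                 channels = chans, totalSpecies = sp[seq_len(n)])
}

#' Gillespie simulation of the multistep chain
#'
#' Exact SSA of the chain with mass-action propensities `a_i = k_i x_i`.
#' The event log (reaction index and firing time) is retained by default;
#' it is what [measureDelays()] consumes.  Grid-sampled counts can be
#' recorded instead for long runs.
#'
#' @param chain a [chainSpec()].
#' @param tEnd end time (> 0); the chain empties in finite time, so a
#'   generous default of `5 * n / min(k)` past the slowest timescale is
#'   used when `tEnd = NULL`.
#' @param seed integer seed.
#' @param recordTimes optional numeric grid at which counts are recorded.
#' @param recordEvents keep the per-event log (default TRUE).
#' @return A list with `trajectory` (a [Trajectory-class] if `recordTimes`
#'   given, else NULL), `events` (data.frame `time`, `channel`), and
#'   `finalState`.
#' @export
ssaChain <- function(chain, tEnd = NULL, seed = 1L, recordTimes = NULL,
                     recordEvents = TRUE) {
  stopifnot(is(chain, "ChainSpec"))
  if (is.null(tEnd)) tEnd <- 5 * chain@n / min(rateConstants(chain)) +
      10 * (chain@x10 + chain@y0 + 1) / min(rateConstants(chain))
  stopifnot(tEnd > 0)
  sys <- chainSystem(chain)
  runSDSSA(sys, tEnd = tEnd, seed = seed, recordTimes = recordTimes,
           recordEvents = recordEvents)
}
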