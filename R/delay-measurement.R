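# Empirical time-delay measurement from exact chain simulations: for each
# consuming firing, the elapsed time until the total chain count first
# drops below the pre-firing X1 count.

# One exhaustion run of the chain, returning the event log; the flattened
# system is reused across replicates by measureDelaysEnsemble.
chainEventRun <- function(flat, tEnd, seed) {
  set.seed(seed)
  .cppRunSDSSA(flat$x0, flat$channels, flat$profiles, flat$initCh,
               flat$initCount, flat$initMT, tEnd, numeric(0), TRUE, 1e8)
}

delayRecordsFromEvents <- function(res, n, x10, y0, replicate) {
  fires <- res$eventTime[res$eventChannel == 1L]
  comps <- res$eventTime[res$eventChannel == n]
  j <- seq_len(x10)
  tau2 <- comps[y0 + j]
  x1At <- x10 - j + 1L
  compBefore <- findInterval(fires, comps, left.open = TRUE)
  yAt <- (x10 + y0 - compBefore) - x1At
  data.frame(replicate = replicate, molecule_index = j, tau1 = fires,
             tau2 = tau2, delay = tau2 - fires, x1_at_firing = x1At,
             y_at_firing = yAt)
}

#' Measure time delays from exact chain simulations
#'
#' Runs the chain SSA to exhaustion and extracts, for the j-th X1 -> X2
#' firing, the firing time tau1, the state snapshot just before the firing
#' (`x1_at_firing`, `y_at_firing`), and tau2: the first time the total
#' chain count (X1..Xn, product excluded) reaches `x1_at_firing - 1`.  The
#' criterion is threshold-based, not particle-tracking: since X1 has no
#' inflow, the j-th firing sees `x1 = x10 - j + 1`, so its threshold is hit
#' at the `(y0 + j)`-th chain completion.
#'
#' @param chain a [chainSpec()] with `x10 >= 1`.
#' @param seed integer seed (one realization per seed).
#' @param replicate replicate id stored in the output.
#' @return data.frame with one row per consuming firing: `replicate`,
#'   `molecule_index`, `tau1`, `tau2`, `delay`, `x1_at_firing`,
#'   `y_at_firing`.
#' @examples
#' measureDelays(chainSpec(n = 3, k = 1, x10 = 5), seed = 7)
#' @export
measureDelays <- function(chain, seed = 1L, replicate = 1L) {
  stopifnot(is(chain, "ChainSpec"), chain@x10 >= 1L)
  flat <- flattenSystem(chainSystem(chain))
  x10 <- chain@x10
  y0 <- chain@y0
  tEnd <- 5 * chain@n / min(rateConstants(chain)) +
    10 * (x10 + y0 + 1) / min(rateConstants(chain))
  repeat {  # run to exhaustion: every molecule must reach the product
    res <- chainEventRun(flat, tEnd, seed)
    if (sum(res$eventChannel == chain@n) == x10 + y0) break
    tEnd <- 4 * tEnd
  }
  delayRecordsFromEvents(res, chain@n, x10, y0, replicate)
}

#' Replicated delay measurement
#'
#' @param chain a [chainSpec()].
#' @param reps number of replicates (default 1000, the scale used for
#'   averaged delay curves).
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @return data.frame of stacked [measureDelays()] records.
#' @export
measureDelaysEnsemble <- function(chain, reps = 1000L, seed = 1L) {
  stopifnot(is(chain, "ChainSpec"), chain@x10 >= 1L, reps >= 1L)
  flat <- flattenSystem(chainSystem(chain))
  x10 <- chain@x10
  y0 <- chain@y0
  tEnd0 <- 5 * chain@n / min(rateConstants(chain)) +
    10 * (x10 + y0 + 1) / min(rateConstants(chain))
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    tEnd <- tEnd0
    repeat {
      res <- chainEventRun(flat, tEnd, seed + r - 1L)
      if (sum(res$eventChannel == chain@n) == x10 + y0) break
      tEnd <- 4 * tEnd
    }
    out[[r]] <- delayRecordsFromEvents(res, chain@n, x10, y0, r)
  }
  do.call(rbind, out)
}

#' Per-molecule-index average of measured delays
#'
#' @param records data.frame from [measureDelays()] /
#'   [measureDelaysEnsemble()].
#' @return data.frame with `molecule_index`, `mean_delay`, `se`, `reps`.
#' @export
averageDelays <- function(records) {
  stopifnot(nrow(records) >= 1L)
  idx <- sort(unique(records$molecule_index))
  out <- do.call(rbind, lapply(idx, function(i) {
    d <- records$delay[records$molecule_index == i]
    data.frame(molecule_index = i, mean_delay = mean(d),
               se = if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0,
               reps = length(d))
  }))
  rownames(out) <- NULL
  out
}
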