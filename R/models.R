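# Builders for the three case studies as ready-to-run SD-SSA systems plus
# their full-chain ground-truth twins.

#' mRNA degradation model (RPL30-style) with state-dependent delay
#'
#' The decay of an mRNA species whose poly(A) tail is shortened through an
#' n = 9 step chain, reduced to the consuming/nonconsuming pair:
#' X1 -> G at rate k*x1 (a full-length transcript enters the shortening
#' process) and the delayed completion G -> P with a state-dependent delay
#' computed from (x1, y) at each firing.  Of the initial `s0` transcripts,
#' `y0` are already in the shortening process; their completions are
#' pre-scheduled uniformly on `[0, MT]` with
#' `MT = tau2ClosedForm(s0 - y0, y0, k, n) / D` (`D > 1`: transcripts
#' already part-way through the chain finish sooner than a fresh one).
#'
#' Defaults are the ACT1-construct estimates `k = 0.1260`, `y0 = 23`,
#' `D = 1.7184` at `s0 = 100`.
#'
#' @param s0 initial total transcript count.
#' @param y0 initial count already in the shortening process
#'   (`0 <= y0 <= s0`).
#' @param k degradation rate constant (1/min).
#' @param D initial-delay adjustment factor (> 1).
#' @param n chain length (default 9: eight poly(A)-shortening steps plus
#'   terminal deadenylation).
#' @param stochasticTau2 sample tau2 around its deterministic value
#'   (Erlang, shape n - 1) instead of using it directly.
#' @return A [reactionSystem()] with species X1 (full-length), G
#'   (in transit) and P; the reported total is X1 + G.
#' @examples
#' sys <- buildRPL30()
#' @export
buildRPL30 <- function(s0 = 100, y0 = 23, k = 0.1260, D = 1.7184, n = 9,
                       stochasticTau2 = FALSE) {
  stopifnot(s0 >= 0, y0 >= 0, y0 <= s0, k > 0, D > 1, n >= 2)
  x10 <- s0 - y0
  sp <- c("X1", "G", "P")
  degrade <- channel(
    name = "degrade", species = sp, rate = k, type = "first",
    reactant = "X1", nu = c(X1 = -1, G = 1), u = c(G = -1, P = 1),
    delay = delayState(k = k, n = n, x1 = "X1", imaginary = "G",
                       stochastic = stochasticTau2))
  sched <- NULL
  if (y0 > 0) {
    mt <- tau2ClosedForm(max(x10, 1), y0, k, n, strict = FALSE) / D
    sched <- data.frame(channel = "degrade", count = y0, mt = mt)
  }
  reactionSystem(species = sp, x0 = c(X1 = x10, G = y0, P = 0),
                 channels = list(degrade), initialSchedule = sched,
                 totalSpecies = c("X1", "G"), units = "min")
}

#' @describeIn buildRPL30 the full 9-step chain twin of the reduced model
#' @export
rpl30Chain <- function(s0 = 100, y0 = 23, k = 0.1260, n = 9) {
  chainSpec(n = n, k = k, x10 = s0 - y0, y0 = y0)
}

#' Default NDD1 activity profile
#'
#' A synthetic periodic transcription-factor activity standing in for the
#' inferred NDD1 concentration: a raised-cosine pulse peaking mid S phase,
#' gated to zero after minute 49 of each cell cycle (mitosis terminates
#' transcription).
#'
#' @param cycleLength cell-cycle length in minutes (default 75).
#' @param peakTime center of the pulse within the cycle (default 25).
#' @param width half-width of the pulse (default 15).
#' @param amplitude peak activity (arbitrary concentration units).
#' @param gateAt activity is zero from this cycle phase onward (default 49).
#' @return A function of time (minutes) returning the activity.
#' @export
ndd1Profile <- function(cycleLength = 75, peakTime = 25, width = 15,
                        amplitude = 10, gateAt = 49) {
  force(cycleLength); force(peakTime); force(width); force(amplitude)
  force(gateAt)
  function(t) {
    phase <- t %% cycleLength
    v <- ifelse(abs(phase - peakTime) < width,
                amplitude * 0.5 * (1 + cos(pi * (phase - peakTime) / width)),
                0)
    ifelse(phase >= gateAt, 0, v)
  }
}

# tabulate a profile function as the step table the engine consumes
tabulateProfile <- function(f, tEnd, dt = 0.25) {
  times <- seq(0, tEnd, by = dt)
  list(times = times, values = f(times))
}

#' Cell-cycle regulated gene expression model (SWI5-style)
#'
#' Transcription activated by the transcription factor NDD1 at rate
#' a*u/(b + u) (u the NDD1 activity), with a constant elongation delay
#' tauTx before the transcript appears in the nucleus; translocation to
#' the cytosol at rate k2 with a constant delay tauLoc; and cytosolic
#' degradation at rate k3 through a state-dependent delay (lumped chain
#' n = 9).  I1, I2, I3 are the imaginary species of the three delayed
#' channels.  NDD1 activity is gated to zero after minute 49 of each cell
#' cycle, which silences transcription.
#'
#' Defaults are the inferred values a = 9.148, b = 3.390, tauTx = 46.665,
#' tauLoc = 0.733, k2 = 2906.04, k3 = 1.297.
#'
#' @param a,b transcriptional regulation parameters.
#' @param tauTx transcription (elongation) delay, minutes.
#' @param tauLoc translocation delay, minutes.
#' @param k2 translocation rate constant (1/min).
#' @param k3 degradation rate constant (1/min).
#' @param ndd1 NDD1 activity: a function of time (see [ndd1Profile()]).
#' @param cycleLength cell-cycle length, minutes.
#' @param tEnd horizon for which the activity profile is tabulated.
#' @param n lumped degradation chain length.
#' @param profileDt tabulation step of the activity profile, minutes.
#' @return A [reactionSystem()] with species mRNA_N, mRNA_C, I1, I2, I3.
#' @export
buildSWI5 <- function(a = 9.148, b = 3.390, tauTx = 46.665, tauLoc = 0.733,
                      k2 = 2906.04, k3 = 1.297,
                      ndd1 = ndd1Profile(cycleLength = cycleLength),
                      cycleLength = 75, tEnd = 150, n = 9,
                      profileDt = 0.25) {
  stopifnot(a > 0, b > 0, tauTx >= 0, tauLoc >= 0, k2 > 0, k3 > 0)
  sp <- c("mRNA_N", "mRNA_C", "I1", "I2", "I3")
  # regulation factor a*u/(b+u), tabulated; the channel itself is
  # zero-order with unit rate times the profile
  reg <- tabulateProfile(function(t) a * ndd1(t) / (b + ndd1(t)),
                         tEnd, profileDt)
  transcribe <- channel(
    name = "transcribe", species = sp, rate = 1, type = "zero",
    profile = "regulation", nu = c(I1 = 1), u = c(I1 = -1, mRNA_N = 1),
    delay = delayConstant(tauTx, imaginary = "I1"))
  translocate <- channel(
    name = "translocate", species = sp, rate = k2, type = "first",
    reactant = "mRNA_N", nu = c(mRNA_N = -1, I2 = 1),
    u = c(I2 = -1, mRNA_C = 1),
    delay = delayConstant(tauLoc, imaginary = "I2"))
  degrade <- channel(
    name = "degrade", species = sp, rate = k3, type = "first",
    reactant = "mRNA_C", nu = c(mRNA_C = -1, I3 = 1), u = c(I3 = -1),
    delay = delayState(k = k3, n = n, x1 = "mRNA_C", imaginary = "I3"))
  reactionSystem(species = sp, x0 = c(mRNA_N = 0, mRNA_C = 0, I1 = 0,
                                      I2 = 0, I3 = 0),
                 channels = list(transcribe, translocate, degrade),
                 profiles = list(regulation = reg),
                 totalSpecies = c("mRNA_N", "mRNA_C"), units = "min")
}

#' Printed parameters of the glucosinolate biosynthesis pathway
#'
#' Maximal rates and equilibrium constants (molecule-number units) of the
#' six chain-elongation reactions E1 -> ... -> E7.
#'
#' @return A list with vectors `V` and `K` of length 6.
#' @export
glucosinolateParams <- function() {
  list(V = c(37.07, 38.27, 73.44, 35.84, 9.31, 2.08),
       K = c(23859200, 12185600, 11852800, 9164800, 6476800, 2073600))
}

#' Aliphatic glucosinolate biosynthesis pathway
#'
#' Six sequential Michaelis-Menten reactions E_i -> E_{i+1} (`mode =
#' "full"`), or the delayed reduction: the first reaction E1 -> U at the
#' (V1, K1) Michaelis-Menten rate plus a delayed completion U -> E7 whose
#' delay is either state-dependent - with the effective per-step rate
#' Vbar/(Kbar + U/5) from the harmonic-mean parameters over steps 2..6 -
#' or a constant (`constantTau`) for the baseline comparison.
#'
#' @param E1 initial substrate count (default 100).
#' @param mode `"full"`, `"state"` (state-dependent delay) or
#'   `"constant"` (constant-delay baseline).
#' @param constantTau constant delay for `mode = "constant"`
#'   (default 3e6).
#' @param V,K per-step parameters (defaults [glucosinolateParams()]).
#' @param stochasticTau2 see [buildRPL30()].
#' @return A [reactionSystem()]; the reported total is the count still in
#'   the pathway (E1..E6, or E1 + U), product excluded.
#' @export
buildGlucosinolate <- function(E1 = 100, mode = c("full", "state", "constant"),
                               constantTau = 3e6,
                               V = glucosinolateParams()$V,
                               K = glucosinolateParams()$K,
                               stochasticTau2 = FALSE) {
  mode <- match.arg(mode)
  stopifnot(E1 >= 0, length(V) == 6, length(K) == 6, all(V > 0), all(K > 0))
  if (mode == "full") {
    sp <- paste0("E", 1:7)
    chans <- lapply(1:6, function(i) {
      nu <- stats::setNames(c(-1, 1), c(sp[i], sp[i + 1]))
      channel(name = paste0("step", i), species = sp, rate = V[i],
              type = "mm", reactant = sp[i], K = K[i], nu = nu)
    })
    return(reactionSystem(species = sp,
                          x0 = stats::setNames(c(E1, rep(0, 6)), sp),
                          channels = chans, totalSpecies = sp[1:6]))
  }
  sp <- c("E1", "U", "E7")
  hm <- harmonicMeans(V[2:6], K[2:6])
  delay <- if (mode == "state")
    delayStateMM(Vbar = hm[["Vbar"]], Kbar = hm[["Kbar"]], n = 6,
                 x1 = "E1", imaginary = "U", stochastic = stochasticTau2)
  else delayConstant(constantTau, imaginary = "U")
  lump <- channel(name = "elongate", species = sp, rate = V[1], type = "mm",
                  reactant = "E1", K = K[1], nu = c(E1 = -1, U = 1),
                  u = c(U = -1, E7 = 1), delay = delay)
  reactionSystem(species = sp, x0 = c(E1 = E1, U = 0, E7 = 0),
                 channels = list(lump), totalSpecies = c("E1", "U"))
}
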